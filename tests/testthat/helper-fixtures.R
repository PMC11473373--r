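# toy builders shared across test files

toy_effects <- function(z, v, ids = sprintf("t%02d", seq_along(z))) {
  effect_table(ids, z, v)
}

# symmetric funnel of 9 effects about z = 0.5; deleting the 3 leftmost
# leaves a set whose one-sided truncation trim-and-fill can detect (k0 = 3)
tf_deletion_fixture <- function() {
  offs <- c(0.21, 0.30, 0.53, 0.78)
  z <- c(0.5, 0.5 + offs, 0.5 - offs)
  v <- c(0.09, 0.26, 0.30, 0.14, 0.13, 0.09, 0.08, 0.24, 0.007)
  o <- order(z)
  list(full = toy_effects(z[o], v[o]),
       deleted = toy_effects(z[o][4:9], v[o][4:9]),
       removed_z = z[o][1:3])
}

# random 3x3 positive-definite correlation matrix via a random Gram matrix
random_pd_triple <- function() {
  repeat {
    A <- matrix(rnorm(9), 3, 3)
    G <- crossprod(A) + diag(3) * 0.05
    d <- 1 / sqrt(diag(G))
    R <- G * tcrossprod(d)
    if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) > 1e-4 &&
        max(abs(R[upper.tri(R)])) < 0.98)
      return(c(xm = R[1, 2], xy = R[1, 3], my = R[2, 3]))
  }
}

# small coding table written inline, for IO tests
toy_coding_csv <- function(path, rows = NULL) {
  header <- "study_id,n,indicator_name,polarity,r_pa_re,r_pa_mh,r_re_mh,population,shares_sample_with"
  writeLines(c(header, rows), path)
  path
}
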