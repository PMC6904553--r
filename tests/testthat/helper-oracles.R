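# Independent oracles used by the tests.  These deliberately avoid the
# package's own code paths: matrix products are written out directly and
# the expected-TRE formula is evaluated from first principles.

# random rigid transform with given frames (uses the current RNG stream)
random_rt <- function(from = "I", to = "P", trans_range = 150) {
  rigid_transform(random_rotation(),
                  stats::runif(3, -trans_range, trans_range), from, to)
}

# first-order expectation of squared TRE for a rigid point registration
# with isotropic fiducial localization error: at target r,
#   E[TRE^2] = (<FLE^2>/N) * (1 + (1/3) * sum_k d_k^2 / f_k^2)
# with d_k the distance of the target from principal axis k of the
# fiducial configuration and f_k the RMS distance of the fiducials from
# that axis.
expected_tre2_oracle <- function(fiducials, target, fle2) {
  N <- nrow(fiducials)
  ctr <- colMeans(fiducials)
  Xc <- sweep(fiducials, 2, ctr)
  ax <- eigen(crossprod(Xc) / N, symmetric = TRUE)$vectors
  f2 <- vapply(1:3, function(k)
    mean(rowSums(Xc^2) - (Xc %*% ax[, k])^2), numeric(1))
  dt <- target - ctr
  d2 <- vapply(1:3, function(k)
    sum(dt^2) - sum(dt * ax[, k])^2, numeric(1))
  (fle2 / N) * (1 + sum(d2 / f2) / 3)
}

# translation recovery error in mm between two rigid transforms
trans_err <- function(a, b) sqrt(sum((a$translation - b$translation)^2))
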