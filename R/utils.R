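# Physical constants (CODATA). Gas constant in kcal mol^-1 K^-1 per the
# free-energy unit convention used throughout the package.
.R_KCAL <- 0.0019872041
.KB_SI <- 1.380649e-23
.H_SI <- 6.62607015e-34

#' Thermal energy kT in kcal/mol
#'
#' @param temperature temperature in Kelvin.
#' @return kT in kcal mol^-1.
#' @export
boltzmann_kt <- function(temperature) {
  stopifnot(is.numeric(temperature), temperature > 0)
  .R_KCAL * temperature
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# log(mean(exp(x))) evaluated stably
log_mean_exp <- function(x) {
  m <- max(x)
  m + log(mean(exp(x - m)))
}

# effective sample size of importance weights exp(x - max)
ess_weights <- function(logw) {
  w <- exp(logw - max(logw))
  sum(w)^2 / sum(w^2)
}

#' Draw a uniformly random 3D rotation matrix
#'
#' Used by the invariance tests: dRMSD and centre-of-mass distances must not
#' change under rigid-body motion of a frame.
#'
#' @return a 3x3 rotation matrix with determinant +1.
#' @export
random_rotation <- function() {
  qr_d <- qr(matrix(rnorm(9), 3, 3))
  q <- qr.Q(qr_d)
  d <- diag(qr.R(qr_d))
  q <- q %*% diag(sign(d))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Apply rotation R and translation t to an xyz row-vector (x1,y1,z1,...)
apply_rigid <- function(xyz_vec, rot, trans = c(0, 0, 0)) {
  m <- matrix(xyz_vec, ncol = 3, byrow = TRUE)
  m <- m %*% t(rot)
  m <- sweep(m, 2, trans, "+")
  as.vector(t(m))
}

# indices of xyz columns for atom indices
atoms2xyz <- function(idx) {
  as.vector(rbind(3 * (idx - 1) + 1, 3 * (idx - 1) + 2, 3 * (idx - 1) + 3))
}

assert_scalar_num <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  invisible(x)
}

# short digest of an R object (provenance metadata) using only base R
object_digest <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf), add = TRUE)
  saveRDS(x, tf, version = 2, compress = FALSE)
  unname(tools::md5sum(tf))
}
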