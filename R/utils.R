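#' @keywords internal
"_PACKAGE"

#' @importFrom rlang abort warn %||% .data
#' @importFrom stats var sd rnorm runif approx quantile aov t.test shapiro.test
#'   predict cov median
#' @importFrom utils head tail
NULL

# Deterministic sub-seed derivation. Keys (participant ids, condition labels,
# iteration counters) are folded into the base seed with a small multiplicative
# hash so that adding runs to a cohort never perturbs existing ones. Result is
# kept strictly inside the 32-bit signed range R requires of set.seed().
derive_seed <- function(seed, ...) {
  keys <- unlist(lapply(list(...), function(k) {
    if (is.character(k)) utf8ToInt(paste(k, collapse = "|")) else as.numeric(k)
  }))
  h <- as.numeric(seed) %% 2147483587
  for (k in keys) {
    h <- (h * 48271 + (as.numeric(k) %% 2147483587) + 1) %% 2147483587
  }
  as.integer(h) + 1L
}

with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

deg2rad <- function(x) x * pi / 180

# Rotation matrices acting on column vectors in (ML, AP, VT) order:
# axis 1 = medio-lateral (right), axis 2 = anterior-posterior (forward),
# axis 3 = vertical (up). Right-handed.
rot_about_ml <- function(rad) { # pitch
  c <- cos(rad); s <- sin(rad)
  matrix(c(1, 0, 0, 0, c, s, 0, -s, c), 3, 3)
}

rot_about_ap <- function(rad) { # roll
  c <- cos(rad); s <- sin(rad)
  matrix(c(c, 0, -s, 0, 1, 0, s, 0, c), 3, 3)
}

rot_about_vt <- function(rad) { # heading / yaw
  c <- cos(rad); s <- sin(rad)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3)
}

# Minimal rotation (Rodrigues) taking unit vector `from` onto unit vector `to`.
rotation_between <- function(from, to) {
  from <- from / sqrt(sum(from^2))
  to <- to / sqrt(sum(to^2))
  v <- c(
    from[2] * to[3] - from[3] * to[2],
    from[3] * to[1] - from[1] * to[3],
    from[1] * to[2] - from[2] * to[1]
  )
  c_ <- sum(from * to)
  s2 <- sum(v^2)
  if (s2 < 1e-24) {
    if (c_ > 0) return(diag(3))
    # antiparallel: rotate pi about any axis orthogonal to `from`
    ortho <- if (abs(from[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    axis <- ortho - sum(ortho * from) * from
    axis <- axis / sqrt(sum(axis^2))
    return(2 * tcrossprod(axis) - diag(3))
  }
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + vx + vx %*% vx * ((1 - c_) / s2)
}

angle_between_deg <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  acos(min(1, max(-1, sum(a * b)))) * 180 / pi
}

is_orthonormal <- function(R, tol = 1e-9) {
  max(abs(crossprod(R) - diag(3))) < tol
}

# Segments are stored 0-based half-open [start, end), matching the on-disk
# JSON sidecar convention. seg_rows() yields the 1-based R row indices.
seg_rows <- function(seg) (seg[1] + 1L):seg[2]

validate_segments <- function(segments, n) {
  if (!length(segments)) abort("at least one segment is required", class = "gaitenv_error")
  prev_end <- 0L
  for (seg in segments) {
    if (length(seg) != 2 || seg[1] < 0 || seg[2] > n || seg[2] <= seg[1]) {
      abort("segments must be non-empty 0-based half-open intervals within the signal",
        class = "gaitenv_error"
      )
    }
    if (seg[1] < prev_end) {
      abort("segments must be disjoint and ordered", class = "gaitenv_error")
    }
    prev_end <- seg[2]
  }
  invisible(segments)
}

assert_that <- function(ok, msg, class = "gaitenv_error") {
  if (!isTRUE(ok)) abort(msg, class = class)
  invisible(TRUE)
}

skewness <- function(x) {
  x <- x - mean(x)
  s <- sqrt(mean(x^2))
  if (s == 0) return(0)
  mean(x^3) / s^3
}
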