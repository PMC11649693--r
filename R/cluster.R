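#' Geometry of the four-package inertial measurement cluster
#'
#' The cluster consists of four accelerometer + gyroscope packages rigidly
#' mounted on a common base. Its geometry is described by the relative
#' position vectors of packages 1-3 with respect to package 0, expressed in
#' the cluster's orthogonal measurement frame. The three vectors must be
#' linearly independent for the angular-acceleration solve to exist; the
#' default geometry places them along near-orthogonal axes with norms
#' 0.08 m, 0.08 m and 0.05 m (the miniaturised prototype dimensions).
#'
#' Sign convention: `r10`, `r20`, `r30` point from package 0 towards packages
#' 1, 2 and 3. This is the convention under which the algebraic solve
#' [cluster_angular_acceleration] exactly inverts the rigid-body forward
#' model [rigid_body_forward_model] in the noise-free case.
#'
#' @param r10,r20,r30 Numeric length-3 vectors, metres.
#' @param cond_cap Maximum acceptable condition number of the triple-product
#'   matrix; geometries above the cap are rejected.
#' @return An object of class `cluster_geometry` with the position vectors,
#'   the precomputed 3x3 solve matrix `M` (rows `(r10 x r20)'`,
#'   `(r20 x r30)'`, `(r30 x r10)'`) and its condition number.
#' @examples
#' geom <- cluster_geometry()
#' geom$condition
#' @export
cluster_geometry <- function(r10 = c(0.08, 0, 0),
                             r20 = c(0, 0.08, 0),
                             r30 = c(0, 0, 0.05),
                             cond_cap = 1e8) {
  for (r in list(r10, r20, r30))
    if (length(r) != 3L || !all(is.finite(r)))
      stop("cluster position vectors must be finite length-3 vectors", call. = FALSE)
  M <- rbind(cross3(r10, r20), cross3(r20, r30), cross3(r30, r10))
  d <- svd(M)$d
  cn <- if (min(d) <= 0) Inf else max(d) / min(d)
  if (!is.finite(cn) || cn > cond_cap)
    stop(sprintf("cluster geometry is numerically singular (condition number %.3g > %.3g)",
                 cn, cond_cap), call. = FALSE)
  structure(list(r10 = r10, r20 = r20, r30 = r30, M = M, condition = cn),
            class = "cluster_geometry")
}

#' @export
print.cluster_geometry <- function(x, ...) {
  cat(sprintf("<cluster_geometry> |r10| = %.3f m, |r20| = %.3f m, |r30| = %.3f m, cond = %.3g\n",
              sqrt(sum(x$r10^2)), sqrt(sum(x$r20^2)), sqrt(sum(x$r30^2)),
              x$condition))
  invisible(x)
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' One time sample of the four-package cluster
#'
#' @param t Time, seconds.
#' @param a List of four numeric length-3 linear-acceleration vectors
#'   (m/s^2), packages 0-3.
#' @param w List of four numeric length-3 angular-velocity vectors (rad/s).
#' @return An object of class `cluster_sample`.
#' @export
cluster_sample <- function(t, a, w) {
  if (!is.list(a) || length(a) != 4L || !is.list(w) || length(w) != 4L)
    stop("a cluster sample needs four acceleration and four angular-velocity readings",
         call. = FALSE)
  for (v in c(a, w))
    if (length(v) != 3L || !all(is.finite(v)))
      stop("cluster readings must be finite length-3 vectors", call. = FALSE)
  structure(list(t = t, a = a, w = w), class = "cluster_sample")
}

#' Mean angular velocity of the cluster
#'
#' The cluster's angular velocity is taken as the component-wise arithmetic
#' mean of the four gyroscope readings, which averages down independent
#' per-package sensor noise.
#'
#' @param sample A [cluster_sample].
#' @return Numeric length-3 angular velocity, rad/s.
#' @export
mean_angular_velocity <- function(sample) {
  if (!inherits(sample, "cluster_sample"))
    stop("`sample` must be a cluster_sample", call. = FALSE)
  (sample$w[[1L]] + sample$w[[2L]] + sample$w[[3L]] + sample$w[[4L]]) / 4
}

#' Solve the cluster angular acceleration
#'
#' Computes the angular acceleration vector of the rigid cluster directly
#' from the four accelerometer readings and the mean angular velocity,
#' without numerical differentiation. With `d_i = a_i - a_0 -
#' omega x (omega x r_i)` the solve is the linear system `M alpha = b` with
#' `b = (d_1 . r20, d_2 . r30, d_3 . r10)'` and `M` the triple-product matrix
#' of [cluster_geometry]; the system is solved directly (no explicit matrix
#' inverse).
#'
#' @param sample A [cluster_sample].
#' @param geom A [cluster_geometry].
#' @return Numeric length-3 angular acceleration `(alpha_x, alpha_y,
#'   alpha_z)`, rad/s^2.
#' @examples
#' geom <- cluster_geometry()
#' s <- rigid_body_forward_model(c(0, 5, 0), c(0, 1, 0), c(0, 0, 9.81), geom)
#' cluster_angular_acceleration(s, geom)
#' @export
cluster_angular_acceleration <- function(sample, geom) {
  if (!inherits(geom, "cluster_geometry"))
    stop("`geom` must be a cluster_geometry", call. = FALSE)
  omega <- mean_angular_velocity(sample)
  a0 <- sample$a[[1L]]
  rs <- list(geom$r10, geom$r20, geom$r30)
  dots <- list(geom$r20, geom$r30, geom$r10)
  b <- vapply(1:3, function(i) {
    d <- sample$a[[i + 1L]] - a0 - cross3(omega, cross3(omega, rs[[i]]))
    sum(d * dots[[i]])
  }, numeric(1))
  drop(solve(geom$M, b))
}

#' Rigid-body forward model of the cluster readings
#'
#' Produces the noise-free accelerometer readings of the four packages for a
#' prescribed rigid-body state, `a_i = a0 + alpha x r_i + omega x (omega x
#' r_i)` with `r_i` the position of package i relative to package 0. Serves
#' as the independent oracle for [cluster_angular_acceleration]: the solve
#' recovers `alpha_true` exactly (to numerical precision) from the forward
#' model's output.
#'
#' @param alpha_true Angular acceleration, rad/s^2 (length 3).
#' @param omega_true Angular velocity, rad/s (length 3), assigned to all four
#'   gyroscopes.
#' @param a0 Linear acceleration of package 0, m/s^2 (length 3).
#' @param geom A [cluster_geometry].
#' @param t Sample time, seconds.
#' @return A [cluster_sample].
#' @export
rigid_body_forward_model <- function(alpha_true, omega_true, a0, geom, t = 0) {
  if (!inherits(geom, "cluster_geometry"))
    stop("`geom` must be a cluster_geometry", call. = FALSE)
  rs <- list(geom$r10, geom$r20, geom$r30)
  a <- c(list(a0), lapply(rs, function(r) {
    a0 + cross3(alpha_true, r) + cross3(omega_true, cross3(omega_true, r))
  }))
  cluster_sample(t, a, w = rep(list(omega_true), 4L))
}

#' Solve a whole cluster recording for trunk kinematics
#'
#' Applies [cluster_angular_acceleration] and [mean_angular_velocity] to each
#' row of a cluster recording and returns the transverse-axis kinematics.
#'
#' @param cluster A cluster recording data frame as returned by
#'   [read_cluster_csv] or [generate_cluster_trial]: column `t` plus columns
#'   `s<i>_ax..s<i>_az` and `s<i>_wx..s<i>_wz` for packages `i = 0..3`.
#' @param geom A [cluster_geometry].
#' @return A [kinematics_series] (with full 3-vector series attached as
#'   attributes `omega` and `alpha`, 3-column matrices).
#' @export
solve_cluster_series <- function(cluster, geom) {
  check_cluster_columns(cluster)
  n <- nrow(cluster)
  acc <- lapply(0:3, function(i)
    as.matrix(cluster[, paste0("s", i, "_a", c("x", "y", "z"))]))
  gyr <- lapply(0:3, function(i)
    as.matrix(cluster[, paste0("s", i, "_w", c("x", "y", "z"))]))
  omega <- (gyr[[1L]] + gyr[[2L]] + gyr[[3L]] + gyr[[4L]]) / 4
  rs <- list(geom$r10, geom$r20, geom$r30)
  dots <- list(geom$r20, geom$r30, geom$r10)
  # vectorised over samples: centripetal term omega x (omega x r) per row
  b <- matrix(0, n, 3L)
  for (i in 1:3) {
    wxr <- row_cross(omega, matrix(rs[[i]], n, 3L, byrow = TRUE))
    cent <- row_cross(omega, wxr)
    d <- acc[[i + 1L]] - acc[[1L]] - cent
    b[, i] <- d %*% dots[[i]]
  }
  alpha <- t(solve(geom$M, t(b)))
  out <- kinematics_series(cluster$t, omega[, 2L], alpha[, 2L])
  attr(out, "omega") <- omega
  attr(out, "alpha") <- alpha
  out
}

row_cross <- function(A, B) {
  cbind(A[, 2L] * B[, 3L] - A[, 3L] * B[, 2L],
        A[, 3L] * B[, 1L] - A[, 1L] * B[, 3L],
        A[, 1L] * B[, 2L] - A[, 2L] * B[, 1L])
}

cluster_column_names <- function() {
  c("t", unlist(lapply(0:3, function(i)
    paste0("s", i, "_", c("ax", "ay", "az", "wx", "wy", "wz")))))
}

check_cluster_columns <- function(cluster) {
  missing_cols <- setdiff(cluster_column_names(), names(cluster))
  if (length(missing_cols) > 0L)
    stop(sprintf("cluster recording lacks column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  invisible(TRUE)
}

#' Read and write raw cluster CSV recordings
#'
#' Format: column `t` (seconds) plus, for each package `i = 0..3`, columns
#' `s<i>_ax s<i>_ay s<i>_az` (m/s^2) and `s<i>_wx s<i>_wy s<i>_wz` (rad/s).
#'
#' @param path Path to a CSV file.
#' @return `read_cluster_csv` returns a validated data frame;
#'   `write_cluster_csv` returns `path` invisibly.
#' @export
read_cluster_csv <- function(path) {
  df <- utils::read.csv(path, check.names = TRUE)
  check_cluster_columns(df)
  check_uniform_grid(df$t)
  df[, cluster_column_names()]
}

#' @rdname read_cluster_csv
#' @param cluster A cluster recording data frame.
#' @export
write_cluster_csv <- function(cluster, path) {
  check_cluster_columns(cluster)
  utils::write.csv(format(cluster[, cluster_column_names()],
                          digits = 15, scientific = FALSE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
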