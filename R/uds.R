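#' Disparities for one-dimensional scaling of electrodes
#'
#' Converts a symmetric connectivity matrix `c` into target disparities for
#' the 1-D scaling objective. The global mode uses `delta = 2 * (1 - c)`
#' (electrodes with strong connectivity are placed close together); the
#' conventional metric form `sqrt(2 * (1 - c))` is available via
#' `sqrt_form = TRUE`. The local mode uses `delta = c^2`, which pushes
#' strongly connected regions apart and groups near-zero correlations.
#'
#' @param conn square symmetric matrix (or [connectivity_matrix()]).
#' @param mode `"global"` or `"local"`.
#' @param sqrt_form use the square-root variant of the global disparity.
#' @param symmetrize how to handle asymmetric input (directed measures):
#'   `"average"` replaces `c` with `(c + t(c)) / 2` with a warning,
#'   `"error"` rejects it.
#' @return Symmetric non-negative disparity matrix with zero diagonal.
#' @export
uds_disparity <- function(conn, mode = c("global", "local"),
                          sqrt_form = FALSE,
                          symmetrize = c("average", "error")) {
  mode <- match.arg(mode)
  symmetrize <- match.arg(symmetrize)
  v <- if (inherits(conn, "connectivity_matrix")) conn$values else as.matrix(conn)
  if (nrow(v) != ncol(v)) stop("connectivity matrix must be square")
  if (max(abs(v - t(v))) > 1e-8) {
    if (symmetrize == "error") stop("connectivity matrix is not symmetric")
    warning("asymmetric connectivity symmetrized as (M + t(M))/2")
    v <- (v + t(v)) / 2
  }
  d <- switch(mode,
              global = if (sqrt_form) sqrt(pmax(2 * (1 - v), 0)) else 2 * (1 - v),
              local = v^2)
  diag(d) <- 0
  d <- pmax(d, 0)
  (d + t(d)) / 2
}

#' Normalized stress of a 1-D embedding
#'
#' `stress(l, delta) = sum_{i<j} (|l_i - l_j| - delta_ij)^2 / sum_{i<j} delta_ij^2`.
#'
#' @param embedding numeric vector of scalar electrode coordinates.
#' @param delta symmetric non-negative disparity matrix.
#' @return Non-negative scalar.
#' @examples
#' uds_stress(c(0, 1), matrix(c(0, 2, 2, 0), 2))  # (1-2)^2 / 2^2 = 0.25
#' @export
uds_stress <- function(embedding, delta) {
  delta <- as.matrix(delta)
  n <- length(embedding)
  if (nrow(delta) != n || ncol(delta) != n)
    stop("embedding and disparity dimensions differ")
  iu <- upper.tri(delta)
  denom <- sum(delta[iu]^2)
  if (denom == 0) stop("all-zero disparities: stress undefined")
  d <- abs(outer(embedding, embedding, "-"))
  sum((d[iu] - delta[iu])^2) / denom
}

# gradient of uds_stress w.r.t. the embedding (subgradient 0 at exact ties)
uds_stress_grad <- function(embedding, delta) {
  iu <- upper.tri(delta)
  denom <- sum(delta[iu]^2)
  diff <- outer(embedding, embedding, "-")
  r <- (abs(diff) - delta) * sign(diff)   # d/dl_i of (|l_i-l_j|-delta)^2 / 2
  diag(r) <- 0
  2 * rowSums(r) / denom
}

#' One-dimensional scaling electrode ordering
#'
#' Embeds electrodes on a line by minimizing the normalized stress
#' ([uds_stress()]) between pairwise embedded distances and mode-specific
#' disparities ([uds_disparity()]), then discards the coordinates and keeps
#' only their rank order. The stress landscape is multimodal, so the
#' optimizer (BFGS with an analytic subgradient) is restarted from
#' `restarts` seeded random configurations plus a classical-scaling start.
#' The returned order is oriented deterministically (the endpoint with the
#' lower channel index comes first); ties in the embedding are broken by
#' ascending channel index.
#'
#' @inheritParams uds_disparity
#' @param seed integer seed for the restarts.
#' @param restarts number of random restarts (default 20).
#' @return An [electrode_order()] with the achieved `stress` and
#'   `embedding` attached.
#' @export
uds_order <- function(conn, mode = c("global", "local"), seed = 1L,
                      restarts = 20L, sqrt_form = FALSE,
                      symmetrize = c("average", "error")) {
  mode <- match.arg(mode)
  delta <- uds_disparity(conn, mode, sqrt_form, symmetrize)
  n <- nrow(delta)
  if (n == 1L) {
    out <- electrode_order(1L, mode)
    out$stress <- 0; out$embedding <- 0
    return(out)
  }
  scale0 <- mean(delta[upper.tri(delta)])
  starts <- list()
  # classical scaling start (first principal coordinate of the disparities)
  cm <- tryCatch(cmdscale(stats::as.dist(delta), k = 1), error = function(e) NULL)
  if (!is.null(cm) && all(is.finite(cm))) starts[[1]] <- as.numeric(cm)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  for (r in seq_len(restarts))
    starts[[length(starts) + 1L]] <- rnorm(n, sd = max(scale0, 1e-3))
  if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    rm(".Random.seed", envir = globalenv())
  best <- NULL
  for (l0 in starts) {
    fit <- tryCatch(
      optim(l0, fn = uds_stress, gr = uds_stress_grad, delta = delta,
            method = "BFGS", control = list(maxit = 500, reltol = 1e-14)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("stress minimization failed from every start")
  l <- best$par
  perm <- order(l, seq_len(n))       # ties -> ascending channel index
  if (perm[1] > perm[n]) perm <- rev(perm)  # canonical orientation
  out <- electrode_order(perm, mode)
  out$stress <- best$value
  out$embedding <- l
  out
}
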