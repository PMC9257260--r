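#' Electrode montage
#'
#' A montage is a set of uniquely named electrodes with 2-D scalp-plane
#' coordinates (unitless projected positions). The package bundles the
#' 32-channel layout used by the DEAP recordings, with 10-20 nomenclature
#' and azimuthal-equidistant projected positions.
#'
#' @param labels character vector of unique electrode names.
#' @param coords numeric matrix (n x 2) of projected positions.
#' @return An object of class `montage`: a data frame with columns
#'   `label`, `x`, `y`.
#' @examples
#' m <- montage(c("A", "B"), cbind(c(0, 1), c(0, 0)))
#' @export
montage <- function(labels, coords) {
  labels <- as.character(labels)
  coords <- as.matrix(coords)
  if (anyDuplicated(labels)) stop("electrode labels must be unique")
  if (nrow(coords) != length(labels) || ncol(coords) != 2)
    stop("coords must be an n x 2 matrix matching labels")
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  out <- data.frame(label = labels, x = coords[, 1], y = coords[, 2],
                    stringsAsFactors = FALSE)
  class(out) <- c("montage", "data.frame")
  out
}

#' The bundled DEAP 32-channel montage
#'
#' Standard 10-20 positions for the 32 EEG channels of the DEAP recordings,
#' in the channel order of the distributed files.
#'
#' @return A [montage()] with 32 electrodes.
#' @export
deap32_montage <- function() {
  path <- system.file("extdata", "deap32_montage.csv", package = "eegdann")
  tab <- read.csv(path, stringsAsFactors = FALSE)
  montage(tab$label, cbind(tab$x, tab$y))
}

#' Canonical scalp-distance electrode chain for the DEAP 32-channel set
#'
#' The distance-driven rearrangement of the 32 DEAP electrodes, starting at
#' Fp1 in the left frontal area and repeatedly stepping to the nearest
#' not-yet-visited electrode. Published 10-20 coordinate tables differ in
#' their 2-D projection, and greedy chaining is sensitive to near-ties, so
#' this chain is shipped as a canonical constant and is authoritative for
#' the `deap32` montage; [order_by_distance()] performs the greedy
#' construction for arbitrary montages.
#'
#' @return Character vector of 32 electrode labels.
#' @export
deap32_chain <- function() {
  c("Fp1", "AF3", "F3", "F7", "FC5", "T7", "CP5", "P7", "P3", "PO3",
    "O1", "Oz", "O2", "PO4", "P4", "P8", "CP6", "T8", "FC6", "F8",
    "F4", "AF4", "Fp2", "Fz", "FC1", "C3", "CP1", "Pz", "CP2", "C4",
    "FC2", "Cz")
}

#' Electrode ordering
#'
#' A permutation of channel indices together with the mode that produced
#' it (`dist`, `global`, `local` or `custom`).
#'
#' @param perm integer permutation of `1:n`.
#' @param mode construction mode.
#' @param labels optional electrode labels (in original channel order).
#' @return An object of class `electrode_order`.
#' @export
electrode_order <- function(perm, mode = c("custom", "dist", "global", "local"),
                            labels = NULL) {
  mode <- match.arg(mode)
  perm <- as.integer(perm)
  n <- length(perm)
  if (!identical(sort(perm), seq_len(n)))
    stop("perm must be a permutation of 1..n")
  structure(list(perm = perm, mode = mode, labels = labels),
            class = "electrode_order")
}

#' @export
print.electrode_order <- function(x, ...) {
  cat(sprintf("<electrode_order> mode=%s, n=%d\n", x$mode, length(x$perm)))
  if (!is.null(x$labels))
    cat(paste(x$labels[x$perm], collapse = " -> "), "\n")
  else cat(paste(x$perm, collapse = " "), "\n")
  invisible(x)
}

#' Greedy nearest-neighbour electrode chain
#'
#' Starting from `start`, repeatedly visits the unvisited electrode closest
#' (Euclidean distance in the projected plane) to the current one. Distance
#' ties are broken by ascending electrode label.
#'
#' @param montage a [montage()].
#' @param start electrode label to start from.
#' @return An [electrode_order()] with mode `"dist"`.
#' @examples
#' m <- montage(c("a", "b", "c"), cbind(c(0, 1, 3), 0))
#' order_by_distance(m, "a")$perm  # 1 2 3
#' @export
order_by_distance <- function(montage, start) {
  stopifnot(inherits(montage, "montage"))
  n <- nrow(montage)
  cur <- match(start, montage$label)
  if (is.na(cur)) stop("unknown start electrode: ", start)
  xy <- cbind(montage$x, montage$y)
  perm <- integer(n)
  visited <- rep(FALSE, n)
  perm[1] <- cur
  visited[cur] <- TRUE
  for (k in seq_len(n - 1L)) {
    rem <- which(!visited)
    d <- sqrt((xy[rem, 1] - xy[cur, 1])^2 + (xy[rem, 2] - xy[cur, 2])^2)
    # order by (distance, label) for deterministic tie-breaking
    nxt <- rem[order(d, montage$label[rem])][1]
    perm[k + 1L] <- nxt
    visited[nxt] <- TRUE
    cur <- nxt
  }
  electrode_order(perm, "dist", labels = montage$label)
}

#' Electrode ordering for the DEAP 32-channel montage
#'
#' Returns the electrode arrangement used to order connectivity-matrix rows
#' and columns. For `mode = "dist"` this is the canonical published chain
#' ([deap32_chain()]); `"global"` and `"local"` orderings are data driven
#' and require a connectivity matrix (see [uds_order()]).
#'
#' @param mode one of `"dist"`, `"global"`, `"local"`.
#' @param conn connectivity matrix, required for the scaling modes.
#' @param ... passed to [uds_order()].
#' @return An [electrode_order()].
#' @export
deap32_order <- function(mode = c("dist", "global", "local"), conn = NULL, ...) {
  mode <- match.arg(mode)
  m <- deap32_montage()
  if (mode == "dist") {
    perm <- match(deap32_chain(), m$label)
    return(electrode_order(perm, "dist", labels = m$label))
  }
  if (is.null(conn)) stop("global/local modes need a connectivity matrix")
  out <- uds_order(conn, mode = mode, ...)
  out$labels <- m$label
  out
}

#' Permute a connectivity matrix by an electrode ordering
#'
#' Applies the same permutation to rows and columns; the measure tag and
#' directedness of a [connectivity_matrix()] are preserved.
#'
#' @param matrix square matrix or [connectivity_matrix()].
#' @param order an [electrode_order()] (or bare permutation vector).
#' @return The permuted matrix, same class as the input.
#' @export
apply_order <- function(matrix, order) {
  perm <- if (inherits(order, "electrode_order")) order$perm else as.integer(order)
  v <- if (inherits(matrix, "connectivity_matrix")) matrix$values else matrix
  if (nrow(v) != length(perm) || ncol(v) != length(perm))
    stop("dimension mismatch between matrix and order")
  pv <- v[perm, perm, drop = FALSE]
  if (!is.null(rownames(v))) {
    rownames(pv) <- rownames(v)[perm]
    colnames(pv) <- colnames(v)[perm]
  }
  if (inherits(matrix, "connectivity_matrix")) {
    matrix$values <- pv
    matrix$order <- if (inherits(order, "electrode_order")) order else
      electrode_order(perm, "custom")
    matrix
  } else pv
}
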