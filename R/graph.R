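#' Electrode layout
#'
#' Named 3-D electrode positions on the scalp. Distance units are those of
#' the coordinate file; the bundled layout is calibrated so that the
#' inverse-square adjacency with `delta = 5` keeps roughly 20% of channel
#' pairs at full weight.
#'
#' @param names character vector of unique electrode labels.
#' @param coords numeric matrix, one row per electrode, columns x, y, z.
#' @return An object of class `electrode_layout`.
#' @export
electrode_layout <- function(names, coords) {
  coords <- as.matrix(coords)
  if (length(names) < 2) stop("need at least 2 electrodes")
  if (anyDuplicated(names)) stop("duplicate electrode names")
  if (nrow(coords) != length(names) || ncol(coords) != 3)
    stop("coords must be an n x 3 matrix matching `names`")
  if (!all(is.finite(coords))) stop("non-finite coordinates")
  rownames(coords) <- names
  structure(list(names = as.character(names), coords = coords),
            class = "electrode_layout")
}

#' @export
print.electrode_layout <- function(x, ...) {
  cat(sprintf("<electrode_layout> %d electrodes: %s ...\n", length(x$names),
              paste(head(x$names, 8), collapse = " ")))
  invisible(x)
}

#' Read an electrode layout from CSV
#'
#' Expects a header `name,x,y,z`.
#'
#' @param path CSV file path.
#' @return An [electrode_layout()].
#' @export
read_layout_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop("layout CSV must have columns: ", paste(need, collapse = ", "))
  electrode_layout(df$name, as.matrix(df[, c("x", "y", "z")]))
}

#' Bundled 62-electrode layout
#'
#' A 10-10 style montage of the 62 channels used by the SEED recording
#' system, placed on a sphere whose radius is calibrated once so that the
#' default inverse-square adjacency keeps about 20% of channel pairs at
#' full weight. `subset` restricts and reorders to a channel subset.
#'
#' @param subset `"all"`, `"seed12"`, or a character vector of names.
#' @return An [electrode_layout()].
#' @export
seed_layout <- function(subset = "all") {
  path <- system.file("extdata", "seed62.csv", package = "sgcsrm")
  lay <- read_layout_csv(path)
  if (length(subset) == 1L && subset == "all") return(lay)
  if (length(subset) == 1L && subset == "seed12") subset <- seed12_channels()
  missing <- setdiff(subset, lay$names)
  if (length(missing))
    stop("electrodes not in bundled layout: ", paste(missing, collapse = ", "))
  electrode_layout(subset, lay$coords[subset, , drop = FALSE])
}

#' Pairwise Euclidean electrode distances
#'
#' @param layout an [electrode_layout()].
#' @return Symmetric C x C distance matrix with zero diagonal.
#' @export
electrode_distances <- function(layout) {
  stopifnot(inherits(layout, "electrode_layout"))
  d <- as.matrix(stats::dist(layout$coords))
  dimnames(d) <- list(layout$names, layout$names)
  off <- d[upper.tri(d)]
  if (any(off == 0))
    warning("distinct electrodes share coordinates (zero distance)")
  d
}

#' Initialise the electrode adjacency matrix
#'
#' Inverse-square decay of connection strength with physical distance:
#' `A[i,j] = min(1, delta / d[i,j]^2)` off the diagonal and `A[i,i] = 1`.
#' With the bundled layout and `delta = 5`, roughly 20% of channel pairs
#' saturate at weight 1.
#'
#' @param dist C x C distance matrix (from [electrode_distances()]).
#' @param delta positive scale of the inverse-square law (default 5).
#' @return Symmetric C x C adjacency matrix with unit diagonal.
#' @export
init_adjacency <- function(dist, delta = 5) {
  stopifnot(is.matrix(dist), nrow(dist) == ncol(dist), delta > 0)
  A <- ifelse(dist > 0, pmin(1, delta / dist^2), 1)
  diag(A) <- 1
  dimnames(A) <- dimnames(dist)
  A
}

#' Symmetric left-right global connection pairs
#'
#' Homologous electrode pairs across the hemispheres whose adjacency
#' entries receive a special initial weight so that differential-asymmetry
#' information is exposed to the graph encoder.
#'
#' @return A two-column character matrix of electrode pairs.
#' @export
global_connection_pairs <- function() {
  cbind(c("FP1", "AF3", "F5", "FC5", "C5", "CP5", "P5", "PO5", "O1"),
        c("FP2", "AF4", "F6", "FC6", "C6", "CP6", "P6", "PO6", "O2"))
}

#' Overwrite adjacency entries for global connections
#'
#' Sets `A[i,j]` and `A[j,i]` to `value` for every pair whose two
#' electrodes are both present; absent pairs are skipped (in the 12-channel
#' subset only C5-C6 and CP5-CP6 remain).
#'
#' @param A adjacency matrix with channel-name dimnames.
#' @param pairs two-column character matrix (default
#'   [global_connection_pairs()]).
#' @param value initial weight for the connections (default -1).
#' @return `A` with the entries overwritten; the applied pairs are attached
#'   as attribute `"applied_pairs"`.
#' @export
apply_global_connections <- function(A, pairs = global_connection_pairs(),
                                     value = -1) {
  stopifnot(is.matrix(A), !is.null(rownames(A)))
  present <- pairs[, 1] %in% rownames(A) & pairs[, 2] %in% rownames(A)
  applied <- pairs[present, , drop = FALSE]
  for (k in seq_len(nrow(applied))) {
    i <- applied[k, 1]; j <- applied[k, 2]
    A[i, j] <- value
    A[j, i] <- value
  }
  attr(A, "applied_pairs") <- applied
  A
}

#' Symmetrically normalised graph operator
#'
#' Computes `S = Dt^(-1/2) (A + I) Dt^(-1/2)` where `Dt` is the diagonal
#' degree of `A + I` taken over absolute values, so the operator stays real
#' when learned or global-connection entries are negative.
#'
#' @param A square adjacency matrix.
#' @return The normalised operator S (same shape as `A`).
#' @export
normalize_adjacency <- function(A) {
  stopifnot(is.matrix(A), nrow(A) == ncol(A))
  At <- A + diag(nrow(A))
  deg <- rowSums(abs(At))
  if (any(deg == 0)) stop("isolated node: zero absolute degree")
  r <- 1 / sqrt(deg)
  S <- At * outer(r, r)
  dimnames(S) <- dimnames(A)
  S
}
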