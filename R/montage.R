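#' Build a spherical EEG montage
#'
#' Places `n_channels` electrodes quasi-uniformly on the upper cap of a
#' sphere of radius `head_radius` using a Fibonacci spiral, builds a
#' nearest-neighbour adjacency graph, and partitions the electrodes into the
#' nine named scalp clusters used by the regional waveform statistics:
#' anterior/central/posterior x left/midline/right (AL, AM, AR, CL, CM, CR,
#' PL, PM, PR).
#'
#' Coordinate convention: +x towards the nasion (anterior), +y towards the
#' left ear, +z towards the vertex.  The cap extends down to
#' `z = cap_zmin * head_radius`, emulating a high-density sensor net after
#' exclusion of the outermost (cheek/neck) belt.
#'
#' @param n_channels number of electrodes (>= 16; 110 emulates a 128-channel
#'   geodesic net reduced by its outer belt).
#' @param head_radius scalp sphere radius in normalized head units.
#' @param cap_zmin lower edge of the electrode cap as a fraction of the
#'   radius (default −0.35, i.e. slightly below the equator).
#' @param k_neighbors number of nearest neighbours each electrode is linked
#'   to before symmetrization of the adjacency graph.
#' @return an object of class `montage`: list with `labels`, `positions`
#'   (n x 3 matrix, rows on the sphere), `head_radius`, `adjacency` (list of
#'   integer neighbour vectors, symmetric), and `clusters` (factor with the
#'   nine levels above).
#' @export
build_montage <- function(n_channels = 110, head_radius = 1.0,
                          cap_zmin = -0.35, k_neighbors = 4) {
  if (n_channels < 16)
    stop("n_channels must be at least 16 to populate nine scalp clusters")
  i <- seq_len(n_channels) - 0.5
  z <- 1 - i * (1 - cap_zmin) / n_channels
  golden <- pi * (3 - sqrt(5))
  phi <- (seq_len(n_channels) - 1) * golden
  rho <- sqrt(pmax(0, 1 - z^2))
  pos <- cbind(x = rho * cos(phi), y = rho * sin(phi), z = z) * head_radius
  labels <- sprintf("E%03d", seq_len(n_channels))
  rownames(pos) <- labels

  adjacency <- knn_adjacency(pos, k_neighbors)
  clusters <- assign_scalp_clusters(pos)
  if (any(table(clusters) == 0L))
    stop("montage has an empty scalp cluster; increase n_channels")

  structure(
    list(labels = labels, positions = pos, head_radius = head_radius,
         adjacency = adjacency, clusters = clusters),
    class = "montage")
}

# Symmetrized k-nearest-neighbour adjacency on electrode positions.
knn_adjacency <- function(pos, k) {
  n <- nrow(pos)
  d <- as.matrix(stats::dist(pos))
  diag(d) <- Inf
  nb <- vector("list", n)
  for (i in seq_len(n)) nb[[i]] <- order(d[i, ])[seq_len(min(k, n - 1L))]
  # symmetrize: j is a neighbour of i if either nominated the other
  for (i in seq_len(n)) for (j in nb[[i]]) {
    if (!(i %in% nb[[j]])) nb[[j]] <- c(nb[[j]], i)
  }
  lapply(nb, function(v) sort(unique(as.integer(v))))
}

# Nine-cluster partition: tertiles along x (anterior/central/posterior),
# then tertiles along y within each band (left/midline/right).  Rank-based
# tertiles guarantee all nine cells are non-empty whenever n >= 9.
assign_scalp_clusters <- function(pos) {
  n <- nrow(pos)
  tertile <- function(v) {
    # rank-based tertiles, highest values in band 1
    m <- length(v)
    r <- rank(-v, ties.method = "first")
    cut(r, breaks = c(0, ceiling(m / 3), ceiling(2 * m / 3), m),
        labels = FALSE)
  }
  xb <- tertile(pos[, 1])          # 1 = anterior, 3 = posterior
  ap <- c("A", "C", "P")[xb]
  lat <- character(n)
  for (b in 1:3) {
    idx <- which(xb == b)
    lat[idx] <- c("L", "M", "R")[tertile(pos[idx, 2])]  # +y = left
  }
  factor(paste0(ap, lat),
         levels = c("AL", "AM", "AR", "CL", "CM", "CR", "PL", "PM", "PR"))
}

#' Write a montage to an .sfp-style text file
#'
#' One electrode per line: `label x y z`, whitespace-delimited.
#'
#' @param montage a [build_montage()] object.
#' @param path output file path.
#' @export
write_sfp <- function(montage, path) {
  df <- data.frame(label = montage$labels,
                   montage$positions, check.names = FALSE)
  utils::write.table(df, path, quote = FALSE, row.names = FALSE,
                     col.names = FALSE, sep = " ")
  invisible(path)
}

#' Read electrode positions from an .sfp-style text file
#'
#' Rebuilds adjacency and the nine-cluster partition from the coordinates.
#'
#' @param path input file path (`label x y z` per line).
#' @param k_neighbors passed to the adjacency construction.
#' @return a `montage` object.
#' @export
read_sfp <- function(path, k_neighbors = 4) {
  df <- utils::read.table(path, header = FALSE,
                          col.names = c("label", "x", "y", "z"))
  pos <- as.matrix(df[, c("x", "y", "z")])
  rownames(pos) <- df$label
  structure(
    list(labels = as.character(df$label), positions = pos,
         head_radius = stats::median(sqrt(rowSums(pos^2))),
         adjacency = knn_adjacency(pos, k_neighbors),
         clusters = assign_scalp_clusters(pos)),
    class = "montage")
}

#' @export
print.montage <- function(x, ...) {
  cat(sprintf("<montage> %d electrodes, head radius %.3g\n",
              length(x$labels), x$head_radius))
  print(table(x$clusters))
  invisible(x)
}
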