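# Linkage map container and map geometry helpers.

#' Construct a linkage map
#'
#' @param chrom Integer chromosome index per marker.
#' @param marker Character marker names, unique genome-wide.
#' @param pos_cM Numeric positions in cM, strictly increasing within each
#'   chromosome.
#' @return A data.frame of class `linkage_map` with columns `chrom`,
#'   `marker`, `pos_cM`, ordered by chromosome and position.
#' @export
linkage_map <- function(chrom, marker, pos_cM) {
  if (length(chrom) != length(marker) || length(marker) != length(pos_cM))
    stop("chrom, marker and pos_cM must have equal length", call. = FALSE)
  if (anyDuplicated(marker))
    stop("marker names must be unique genome-wide", call. = FALSE)
  df <- data.frame(chrom = as.integer(chrom), marker = as.character(marker),
                   pos_cM = as.numeric(pos_cM), stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$pos_cM), , drop = FALSE]
  rownames(df) <- NULL
  for (c_ in unique(df$chrom)) {
    p <- df$pos_cM[df$chrom == c_]
    if (any(diff(p) <= 0))
      stop("marker positions must be strictly increasing within a chromosome",
           call. = FALSE)
  }
  class(df) <- c("linkage_map", "data.frame")
  df
}

#' Default simulation linkage map
#'
#' Five chromosomes of 11 evenly spaced markers each (10 cM spacing,
#' 0--100 cM), 55 markers in total: the standard genome used throughout
#' the package's simulation studies.
#'
#' @param n_chrom Number of chromosomes.
#' @param n_markers Markers per chromosome.
#' @param spacing_cM Marker spacing in cM.
#' @return A `linkage_map`.
#' @export
default_linkage_map <- function(n_chrom = 5, n_markers = 11, spacing_cM = 10) {
  chrom <- rep(seq_len(n_chrom), each = n_markers)
  pos <- rep(seq(0, by = spacing_cM, length.out = n_markers), n_chrom)
  marker <- sprintf("M%d_%d", chrom, rep(seq_len(n_markers), n_chrom))
  linkage_map(chrom, marker, pos)
}

# Marker intervals of a map: one row per pair of adjacent markers, with
# global marker column indices.
.map_intervals <- function(map) {
  out <- do.call(rbind, lapply(unique(map$chrom), function(c_) {
    idx <- which(map$chrom == c_)
    if (length(idx) < 2) return(NULL)
    data.frame(chrom = c_,
               left = idx[-length(idx)], right = idx[-1],
               lpos = map$pos_cM[idx[-length(idx)]],
               rpos = map$pos_cM[idx[-1]])
  }))
  out$interval <- seq_len(nrow(out))
  out
}

# Interval containing a position; positions at a shared marker boundary are
# assigned to the right interval except at the chromosome end.
.find_interval <- function(intervals, chrom, pos) {
  iv <- intervals[intervals$chrom == chrom, , drop = FALSE]
  if (nrow(iv) == 0L) stop("no intervals on chromosome ", chrom, call. = FALSE)
  if (pos < iv$lpos[1] - 1e-9 || pos > iv$rpos[nrow(iv)] + 1e-9)
    stop("position ", pos, " outside the mapped span of chromosome ", chrom,
         call. = FALSE)
  hit <- which(pos >= iv$lpos - 1e-9 & pos < iv$rpos - 1e-9)
  if (length(hit) == 0L) hit <- nrow(iv)
  iv$interval[hit[1]]
}

# Genome-wide scan grid at a given step, clipped to each chromosome's span.
.scan_grid <- function(map, step_cM) {
  if (step_cM <= 0) stop("step_cM must be positive", call. = FALSE)
  intervals <- .map_intervals(map)
  out <- do.call(rbind, lapply(unique(map$chrom), function(c_) {
    p <- map$pos_cM[map$chrom == c_]
    grid <- unique(c(seq(min(p), max(p), by = step_cM), max(p)))
    data.frame(chrom = c_, pos_cM = grid)
  }))
  out$interval <- vapply(seq_len(nrow(out)), function(i)
    .find_interval(intervals, out$chrom[i], out$pos_cM[i]), integer(1))
  rownames(out) <- NULL
  out
}

# Gap in cM between two marker intervals (0 if overlapping/adjacent);
# Inf across chromosomes.
.interval_gap <- function(intervals, i, j) {
  a <- intervals[intervals$interval == i, ]
  b <- intervals[intervals$interval == j, ]
  if (a$chrom != b$chrom) return(Inf)
  max(0, max(a$lpos, b$lpos) - min(a$rpos, b$rpos))
}
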