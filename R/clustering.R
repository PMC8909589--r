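#' Build a lesion table
#'
#' A lesion is an elementary DNA damage: a strand break or a base damage at a
#' base-pair position on one strand. Lesion tables are plain data frames with
#' columns `position`, `strand` and `kind`, ordered by position.
#'
#' @param position Integer base-pair indices (>= 0).
#' @param strand `"forward"` or `"reverse"`, recycled.
#' @param kind `"strand_break"` or `"base_damage"`, recycled.
#' @return A data frame of lesions sorted by position.
#' @examples
#' lesions(c(0, 5), c("forward", "reverse"), "strand_break")
#' @export
lesions <- function(position, strand = "forward", kind = "strand_break") {
  if (length(position) == 0L) {
    return(data.frame(position = integer(), strand = character(),
                      kind = character()))
  }
  if (any(position < 0)) stop("lesion positions must be >= 0")
  strand <- rep_len(as.character(strand), length(position))
  kind <- rep_len(as.character(kind), length(position))
  if (!all(strand %in% c("forward", "reverse"))) {
    stop("strand must be 'forward' or 'reverse'")
  }
  if (!all(kind %in% c("strand_break", "base_damage"))) {
    stop("kind must be 'strand_break' or 'base_damage'")
  }
  out <- data.frame(position = as.integer(position), strand = strand,
                    kind = kind, stringsAsFactors = FALSE)
  out[order(out$position), , drop = FALSE]
}

#' Group lesions into damage clusters
#'
#' Consecutive lesions separated by fewer than `n_min_bp` base pairs belong to
#' the same cluster; a positional gap of at least `n_min_bp` starts a new
#' cluster. The default threshold of 9 bp mirrors the damage-grouping rule of
#' fast Monte Carlo damage simulators.
#'
#' @param lesion_table Data frame of lesions sorted by position (see
#'   [lesions()]).
#' @param n_min_bp Minimum separation (bp) at which two lesions are treated as
#'   belonging to different clusters.
#' @return A list of lesion data frames, one per cluster, in genomic order.
#' @examples
#' cluster_lesions(lesions(c(0, 5, 20, 24)), n_min_bp = 9)
#' @export
cluster_lesions <- function(lesion_table, n_min_bp = 9) {
  if (n_min_bp < 1) stop("n_min_bp must be >= 1")
  l <- as.data.frame(lesion_table)
  if (nrow(l) == 0L) return(list())
  if (is.unsorted(l$position)) stop("lesions must be sorted by position")
  id <- cumsum(c(TRUE, diff(l$position) >= n_min_bp))
  unname(split(l, id))
}

#' Count double-strand-break pairings in a cluster
#'
#' Maximum number of disjoint pairs of opposite-strand breaks whose positions
#' differ by at most `window` base pairs. Because pairings never cross when
#' both strands are scanned in genomic order, a two-pointer greedy scan
#' attains the maximum matching.
#'
#' @param forward_pos,reverse_pos Strand-break positions on each strand.
#' @param window Pairing window in base pairs.
#' @return Integer number of DSB pairings.
#' @export
count_dsb_pairs <- function(forward_pos, reverse_pos, window = 10) {
  f <- sort(forward_pos)
  r <- sort(reverse_pos)
  i <- 1L; j <- 1L; n <- 0L
  while (i <= length(f) && j <= length(r)) {
    d <- f[i] - r[j]
    if (abs(d) <= window) {
      n <- n + 1L; i <- i + 1L; j <- j + 1L
    } else if (d < 0) {
      i <- i + 1L
    } else {
      j <- j + 1L
    }
  }
  n
}

#' Classify one damage cluster
#'
#' Assigns a cluster of lesions to one of the seven damage classes (see
#' [damage_classes()]). Opposite-strand breaks within `dsb_window_bp` base
#' pairs constitute a double-strand break; opposite-strand breaks further
#' apart are counted as `2SSB`.
#'
#' @param cluster A lesion data frame (one cluster, sorted by position).
#' @param dsb_window_bp Opposite-strand pairing window in base pairs.
#' @return One of `"BD"`, `"SSB"`, `"SSB+"`, `"2SSB"`, `"DSB"`, `"DSB+"`,
#'   `"DSB++"`.
#' @examples
#' classify_cluster(lesions(c(0, 5), c("forward", "reverse")))   # DSB
#' classify_cluster(lesions(c(0, 15), c("forward", "reverse")))  # 2SSB
#' @export
classify_cluster <- function(cluster, dsb_window_bp = 10) {
  cl <- as.data.frame(cluster)
  if (nrow(cl) == 0L) stop("cannot classify an empty cluster")
  if (dsb_window_bp < 1) stop("dsb_window_bp must be >= 1")
  if (is.unsorted(cl$position)) stop("lesions must be sorted by position")
  sb <- cl$kind == "strand_break"
  f <- cl$position[sb & cl$strand == "forward"]
  r <- cl$position[sb & cl$strand == "reverse"]
  n_sb <- length(f) + length(r)
  if (n_sb == 0L) return("BD")
  if (n_sb == 1L) return("SSB")
  if (length(f) == 0L || length(r) == 0L) return("SSB+")
  np <- count_dsb_pairs(f, r, dsb_window_bp)
  if (np == 0L) return("2SSB")
  if (np >= 2L) return("DSB++")
  if (n_sb == 2L) "DSB" else "DSB+"
}
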