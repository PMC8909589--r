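# Independent brute-force oracles for lesion clustering and cluster
# classification, used to cross-check the package implementation. The
# clusterer builds the full proximity graph and extracts connected
# components; the classifier finds the maximum DSB pairing by exhaustive
# recursion. Both avoid the package's sorted-scan shortcuts.

oracle_cluster <- function(df, n_min = 9) {
  n <- nrow(df)
  if (n == 0L) return(list())
  adj <- abs(outer(df$position, df$position, "-")) < n_min
  comp <- integer(n)
  nc <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      nc <- nc + 1L
      queue <- i
      while (length(queue)) {
        v <- queue[1L]
        queue <- queue[-1L]
        if (comp[v] == 0L) {
          comp[v] <- nc
          queue <- c(queue, which(adj[v, ] & comp == 0L))
        }
      }
    }
  }
  lapply(split(seq_len(n), comp), function(ix) df[ix, , drop = FALSE])
}

oracle_max_match <- function(f, r, w) {
  if (length(f) == 0L || length(r) == 0L) return(0L)
  best <- oracle_max_match(f[-1L], r, w)
  for (k in seq_along(r)) {
    if (abs(f[1L] - r[k]) <= w) {
      best <- max(best, 1L + oracle_max_match(f[-1L], r[-k], w))
    }
  }
  best
}

oracle_classify <- function(cl, window = 10) {
  sb <- cl$kind == "strand_break"
  f <- cl$position[sb & cl$strand == "forward"]
  r <- cl$position[sb & cl$strand == "reverse"]
  ns <- length(f) + length(r)
  if (ns == 0L) return("BD")
  if (ns == 1L) return("SSB")
  if (length(f) == 0L || length(r) == 0L) return("SSB+")
  m <- oracle_max_match(f, r, window)
  if (m == 0L) return("2SSB")
  if (m >= 2L) return("DSB++")
  if (ns == 2L) "DSB" else "DSB+"
}

cluster_signature <- function(cl) {
  paste(sort(paste(cl$position, cl$strand, cl$kind, sep = "/")),
        collapse = ";")
}

# Run both pipelines on a lesion table and report whether cluster
# memberships and the multiset of class labels agree.
pipelines_agree <- function(df, n_min = 9, window = 10) {
  ours <- cluster_lesions(df, n_min)
  theirs <- oracle_cluster(df, n_min)
  sig_ours <- sort(unname(vapply(ours, cluster_signature, character(1))))
  sig_theirs <- sort(unname(vapply(theirs, cluster_signature, character(1))))
  if (!identical(sig_ours, sig_theirs)) return(FALSE)
  lab_ours <- sort(unname(vapply(ours, classify_cluster, character(1),
                                 dsb_window_bp = window)))
  lab_theirs <- sort(unname(vapply(theirs, oracle_classify, character(1),
                                   window = window)))
  identical(lab_ours, lab_theirs)
}

random_lesion_table <- function(n, max_pos = 39) {
  lesions(sample(0:max_pos, n, replace = TRUE),
          sample(c("forward", "reverse"), n, replace = TRUE),
          sample(c("strand_break", "base_damage"), n, replace = TRUE))
}

# All single-lesion and two-lesion configurations on a segment.
enumerate_small_cases <- function(max_pos = 39) {
  atoms <- expand.grid(position = 0:max_pos,
                       strand = c("forward", "reverse"),
                       kind = c("strand_break", "base_damage"),
                       stringsAsFactors = FALSE)
  singles <- lapply(seq_len(nrow(atoms)), function(i) {
    lesions(atoms$position[i], atoms$strand[i], atoms$kind[i])
  })
  idx <- utils::combn(nrow(atoms), 2L)
  pairs <- lapply(seq_len(ncol(idx)), function(k) {
    i <- idx[1L, k]; j <- idx[2L, k]
    lesions(atoms$position[c(i, j)], atoms$strand[c(i, j)],
            atoms$kind[c(i, j)])
  })
  c(singles, pairs)
}
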