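#' Dwt: composite topology-weighting scan statistic
#'
#' For per-window topology weightings of the species-tree topology
#' (`w_sptree`) and the two discordant topologies (`w_disc1`, the putative
#' introgression topology, and `w_disc2`):
#'
#' `Dwt = ((disc1 - disc2) / (disc1 + disc2)) *
#'        ((max(sptree, disc1, disc2) - sptree) /
#'         (max(sptree, disc1, disc2) + sptree))`
#'
#' Dwt is 0 whenever the species tree carries the highest weighting, rises to
#' 1 when the introgression topology is fully supported, and falls to -1 when
#' the other discordant topology is fully supported. When
#' `disc1 + disc2 = 0` the first factor is taken as 0. All-zero weightings
#' (data-empty windows) are undefined and return `NA`.
#'
#' Vectorized over windows.
#'
#' @param w_sptree,w_disc1,w_disc2 non-negative weightings (need not be
#'   normalized).
#' @return numeric Dwt in `[-1, 1]` (`NA` where undefined).
#' @export
dwt <- function(w_sptree, w_disc1, w_disc2) {
  n <- length(w_sptree)
  stopifnot(length(w_disc1) == n, length(w_disc2) == n)
  if (any(w_sptree < 0 | w_disc1 < 0 | w_disc2 < 0, na.rm = TRUE))
    stop("topology weightings must be non-negative")
  tot <- w_sptree + w_disc1 + w_disc2
  dsum <- w_disc1 + w_disc2
  f1 <- ifelse(dsum > 0, (w_disc1 - w_disc2) / dsum, 0)
  mx <- pmax(w_sptree, w_disc1, w_disc2)
  f2 <- ifelse(mx + w_sptree > 0, (mx - w_sptree) / (mx + w_sptree), NA_real_)
  out <- f1 * f2
  out[is.na(tot) | tot == 0] <- NA_real_
  out
}

#' Per-window Dwt track
#'
#' @param weights data.frame with columns `chrom`, `start`, `end` (half-open
#'   bp, sorted and non-overlapping within chromosome), `w_sptree`,
#'   `w_disc1`, `w_disc2`. All-zero (data-empty) windows propagate `NA`.
#' @return the input data.frame with a `dwt` column, class `dwt_track`.
#' @export
dwt_track <- function(weights) {
  need <- c("chrom", "start", "end", "w_sptree", "w_disc1", "w_disc2")
  stopifnot(all(need %in% names(weights)))
  for (ch in unique(weights$chrom)) {
    w <- weights[weights$chrom == ch, ]
    if (is.unsorted(w$start, strictly = TRUE))
      stop("windows must be sorted within chromosome ", ch)
    if (any(w$start[-1L] < w$end[-nrow(w)]))
      stop("windows overlap within chromosome ", ch)
  }
  weights$dwt <- dwt(weights$w_sptree, weights$w_disc1, weights$w_disc2)
  class(weights) <- c("dwt_track", class(weights))
  weights
}

# merge sorted-or-unsorted intervals given as bare vectors
merge_iv <- function(s, e) {
  o <- order(s)
  s <- s[o]; e <- e[o]
  if (length(s) > 1L) {
    me <- cummax(e)
    grp <- cumsum(c(TRUE, s[-1L] > me[-length(me)]))
    s <- s[!duplicated(grp)]
    e <- as.numeric(tapply(e, grp, max))
  }
  list(start = s, end = e)
}

# overlapped bp between two merged interval lists on the same chromosome
overlap_iv <- function(a, b) {
  cum <- c(0, cumsum(a$end - a$start))
  cov_at <- function(x) {
    i <- findInterval(x, a$start)
    out <- numeric(length(x))
    pos <- i > 0L
    ii <- i[pos]
    out[pos] <- cum[ii] + pmin(pmax(x[pos] - a$start[ii], 0),
                               a$end[ii] - a$start[ii])
    out
  }
  sum(cov_at(b$end) - cov_at(b$start))
}

# sort + merge intervals; touching intervals are merged
normalize_regions <- function(x) {
  if (nrow(x) == 0L)
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0)))
  stopifnot(all(x$end > x$start))
  out <- lapply(sort(unique(x$chrom)), function(ch) {
    sel <- x$chrom == ch
    m <- merge_iv(x$start[sel], x$end[sel])
    data.frame(chrom = ch, start = m$start, end = m$end)
  })
  ans <- do.call(rbind, out)
  rownames(ans) <- NULL
  ans
}

#' Extract consistently introgressed regions from a Dwt track
#'
#' Maximal runs of contiguous windows (window end equal to the next window's
#' start, same chromosome) whose Dwt lies within `tol` of `required_value`
#' are merged; runs spanning fewer than `min_span_bp` base pairs are
#' discarded. With the defaults this extracts stretches of at least 50 kb
#' where the scan consistently has Dwt = 1.0.
#'
#' @param track a [dwt_track()].
#' @param required_value Dwt value a window must attain (default 1.0).
#' @param tol tolerance on the match (default 1e-9; widen for noisy tracks).
#' @param min_span_bp minimum region span in bp (default 50000).
#' @return data.frame of regions (`chrom`, `start`, `end`), half-open,
#'   merged and sorted.
#' @export
consistent_regions <- function(track, required_value = 1.0, tol = 1e-9,
                               min_span_bp = 50000L) {
  stopifnot(inherits(track, "dwt_track"))
  hit <- !is.na(track$dwt) & abs(track$dwt - required_value) <= tol
  regions <- list()
  i <- 1L
  n <- nrow(track)
  while (i <= n) {
    if (!hit[i]) { i <- i + 1L; next }
    j <- i
    while (j < n && hit[j + 1L] && track$chrom[j + 1L] == track$chrom[j] &&
           track$start[j + 1L] == track$end[j]) j <- j + 1L
    span <- track$end[j] - track$start[i]
    if (span >= min_span_bp)
      regions[[length(regions) + 1L]] <-
        data.frame(chrom = track$chrom[i], start = track$start[i],
                   end = track$end[j])
    i <- j + 1L
  }
  normalize_regions(if (length(regions)) do.call(rbind, regions)
                    else data.frame(chrom = character(0), start = numeric(0),
                                    end = numeric(0)))
}

#' Total overlap (bp) between two region sets
#'
#' Both sets are normalized (sorted, merged) before intersecting.
#'
#' @param a,b region data.frames (`chrom`, `start`, `end`, half-open).
#' @return total intersected base pairs.
#' @export
region_overlap <- function(a, b) {
  a <- normalize_regions(a)
  b <- normalize_regions(b)
  if (nrow(a) == 0L || nrow(b) == 0L) return(0)
  total <- 0
  for (ch in intersect(a$chrom, b$chrom)) {
    sa <- a$chrom == ch
    sb <- b$chrom == ch
    total <- total + overlap_iv(list(start = a$start[sa], end = a$end[sa]),
                                list(start = b$start[sb], end = b$end[sb]))
  }
  total
}

#' Permutation test for overlap between two region sets
#'
#' The observed overlap of `a` and `b` is compared to a null in which each
#' interval of `b` is independently re-placed uniformly at random within its
#' chromosome (length preserved; integer start; overlaps among placed
#' intervals allowed). The overlap statistic scores each of `b`'s intervals
#' against `a` independently — identical to the merged intersection whenever
#' `b` is disjoint (as region sets from [consistent_regions()] are), and the
#' form that makes the observed and permuted statistics exactly
#' exchangeable. The p-value uses the add-one estimator
#' `(count >= observed + 1) / (n_perm + 1)`.
#'
#' @param a,b region data.frames.
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed.
#' @return list with `observed`, `p`, `null` (numeric vector of permuted
#'   overlaps), `n_perm`.
#' @export
overlap_permutation_test <- function(a, b, chrom_lengths, n_perm = 10000L,
                                     seed = 1L) {
  a <- normalize_regions(a)
  if (nrow(b) == 0L)
    return(list(observed = 0, p = 1, null = rep(0, n_perm), n_perm = n_perm))
  stopifnot(all(b$end > b$start))
  if (!all(b$chrom %in% names(chrom_lengths)) ||
      !all(a$chrom %in% names(chrom_lengths)))
    stop("all regions must lie on named chromosomes")
  len <- b$end - b$start
  maxstart <- chrom_lengths[b$chrom] - len
  if (any(maxstart < 0)) stop("interval longer than its chromosome")
  set.seed(as.integer(seed))
  chroms <- unique(b$chrom)
  a_by_chrom <- lapply(chroms, function(ch) {
    sel <- a$chrom == ch
    list(start = a$start[sel], end = a$end[sel])
  })
  names(a_by_chrom) <- chroms
  b_chrom <- b$chrom
  score <- function(s) {
    tot <- 0
    for (ch in chroms) {
      av <- a_by_chrom[[ch]]
      if (length(av$start) == 0L) next
      sel <- b_chrom == ch
      tot <- tot + overlap_iv(av, list(start = s[sel],
                                       end = s[sel] + len[sel]))
    }
    tot
  }
  observed <- score(b$start)
  null <- vapply(seq_len(n_perm), function(i)
    score(floor(runif(nrow(b)) * (maxstart + 1))), numeric(1))
  list(observed = observed, p = (sum(null >= observed) + 1) / (n_perm + 1),
       null = null, n_perm = n_perm)
}

#' Write regions as BED (0-based half-open)
#'
#' @param regions region data.frame.
#' @param path output path.
#' @param header optional `#`-prefixed header lines.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("#", header), con)
  if (nrow(regions))
    writeLines(paste(regions$chrom, format(regions$start, scientific = FALSE,
                                           trim = TRUE),
                     format(regions$end, scientific = FALSE, trim = TRUE),
                     sep = "\t"), con)
  invisible(path)
}
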