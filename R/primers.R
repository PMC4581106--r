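# Constrained primer design around a target interval. Feasibility of a
# primer window depends only on its length and G+C count (the melting
# temperature model is the GC-fraction formula), which lets the search
# precompute, per transcript, the minimal feasible primer length at every
# start/end position from a cumulative GC vector, and then resolve each
# target with pure arithmetic.

#' Primer design constraints
#'
#' Defaults are the published SSR-primer parameters: amplicon 100-280 bp,
#' annealing temperature 55-65 degrees C, primer length 18-28 nt, GC
#' content 45-55 percent.
#'
#' @param amp_min,amp_max amplicon (product) size range, bp.
#' @param tm_min,tm_max melting-temperature window, degrees C.
#' @param len_min,len_max primer length range, nt.
#' @param gc_min,gc_max GC content range, percent of primer length.
#' @return List of class \code{primer_params}.
#' @export
primer_params <- function(amp_min = 100L, amp_max = 280L,
                          tm_min = 55, tm_max = 65,
                          len_min = 18L, len_max = 28L,
                          gc_min = 45, gc_max = 55) {
  p <- list(amp_min = as.integer(amp_min), amp_max = as.integer(amp_max),
            tm_min = tm_min, tm_max = tm_max,
            len_min = as.integer(len_min), len_max = as.integer(len_max),
            gc_min = gc_min, gc_max = gc_max)
  if (p$amp_min > p$amp_max || p$tm_min > p$tm_max ||
      p$len_min > p$len_max || p$gc_min > p$gc_max)
    stop("each constraint range needs min <= max")
  class(p) <- "primer_params"
  p
}

#' Melting temperature of a primer
#'
#' GC-fraction formula: Tm = 64.9 + 41 (nG + nC - 16.4) / length. Defined
#' for primers of at least 14 nt.
#'
#' @param primer DNA string (length >= 14).
#' @return Temperature in degrees C.
#' @export
#' @examples
#' melting_temperature("ACGTACGTACGGCCGGCCAT")
melting_temperature <- function(primer) {
  n <- nchar(primer)
  if (any(n < 14L)) stop("primer shorter than 14 nt")
  gc <- nchar(gsub("[^GCgc]", "", primer))
  64.9 + 41 * (gc - 16.4) / n
}

#' GC content of a sequence, percent
#' @param x DNA string(s).
#' @export
gc_content <- function(x) {
  100 * nchar(gsub("[^GCgc]", "", x)) / nchar(x)
}

# Precompute, for every window anchor, the minimal feasible primer length.
# fwd_min[s]: smallest len with window [s, s+len-1] satisfying GC and Tm;
# rev_min[e]: same for window [e-len+1, e] (the reverse primer is the
# reverse complement of that window; GC count, hence Tm, is unchanged).
.primer_index <- function(seq, params) {
  x <- strsplit(toupper(seq), "")[[1]]
  L <- length(x)
  cum <- c(0L, cumsum(x %in% c("G", "C")))
  fwd <- rep(NA_integer_, L)
  rev <- rep(NA_integer_, L)
  for (len in params$len_min:params$len_max) {
    if (len > L) break
    starts <- seq_len(L - len + 1L)
    g <- cum[starts + len] - cum[starts]
    gc_pct <- 100 * g / len
    tm <- 64.9 + 41 * (g - 16.4) / len
    ok <- gc_pct >= params$gc_min & gc_pct <= params$gc_max &
      tm >= params$tm_min & tm <= params$tm_max
    s_ok <- starts[ok]
    fwd[s_ok][is.na(fwd[s_ok])] <- len
    e_ok <- s_ok + len - 1L
    rev[e_ok][is.na(rev[e_ok])] <- len
  }
  list(x = x, L = L, fwd_min = fwd, rev_min = rev)
}

.subseq <- function(x, from, to) paste(x[from:to], collapse = "")

# assemble the primer-pair record for a chosen (product start, product end)
.pair_record <- function(idx, s, e, fl, rl) {
  fwd_seq <- .subseq(idx$x, s, s + fl - 1L)
  rev_win <- .subseq(idx$x, e - rl + 1L, e)
  list(product_start = s, product_end = e, product_size = e - s + 1L,
       forward = fwd_seq, reverse = revcomp(rev_win),
       forward_tm = melting_temperature(fwd_seq),
       reverse_tm = melting_temperature(revcomp(rev_win)))
}

# Candidate forward starts / reverse ends flanking [t_s, t_e], with the
# minimal feasible primer length that stays clear of the target.
.flank_candidates <- function(idx, t_s, t_e, params) {
  L <- idx$L
  s_lo <- max(1L, t_e - params$amp_max + 1L)
  s_hi <- t_s - params$len_min
  Fs <- integer(0)
  if (s_hi >= s_lo) {
    cand <- s_lo:s_hi
    fl <- idx$fwd_min[cand]
    keep <- !is.na(fl) & (cand + fl - 1L) < t_s
    Fs <- cand[keep]
  }
  e_lo <- t_e + params$len_min
  e_hi <- min(L, t_s + params$amp_max - 1L)
  Re <- integer(0)
  if (e_hi >= e_lo) {
    cand <- e_lo:e_hi
    rl <- idx$rev_min[cand]
    keep <- !is.na(rl) & (cand - rl + 1L) > t_e
    Re <- cand[keep]
  }
  list(Fs = Fs, Re = Re)
}

#' Design a primer pair flanking a target interval
#'
#' The forward primer lies strictly upstream of the target and the reverse
#' primer is the reverse complement of a window strictly downstream; both
#' satisfy the length, GC and Tm constraints and the product size lies in
#' the amplicon range while covering the target. The choice is
#' deterministic: smallest product first, then the most-centered target,
#' then the leftmost product; each primer takes its smallest feasible
#' length.
#'
#' @param seq transcript sequence.
#' @param target_start,target_end 1-based inclusive target interval.
#' @param params a \code{\link{primer_params}}.
#' @return On success a list with product coordinates and primer
#'   sequences/Tms; on failure a list with \code{rejected = "NO_PRIMER"}
#'   and the binding constraint in \code{detail}.
#' @export
design_primers <- function(seq, target_start, target_end,
                           params = primer_params()) {
  L <- nchar(seq)
  if (target_start < 1L || target_end > L || target_start > target_end)
    stop("target interval outside transcript")
  idx <- .primer_index(seq, params)
  fc <- .flank_candidates(idx, target_start, target_end, params)
  if (!length(fc$Fs) || !length(fc$Re)) {
    detail <- if (!length(fc$Fs)) "no feasible forward primer window"
    else "no feasible reverse primer window"
    return(list(rejected = "NO_PRIMER", detail = detail))
  }
  re_ok <- rep(FALSE, idx$L)
  re_ok[fc$Re] <- TRUE
  t_mid <- (target_start + target_end) / 2
  for (P in params$amp_min:params$amp_max) {
    e <- fc$Fs + P - 1L
    hit <- e <= idx$L & re_ok[pmin(e, idx$L)]
    if (!any(hit)) next
    s_cand <- fc$Fs[hit]
    cen <- abs((s_cand + (s_cand + P - 1L)) / 2 - t_mid)
    s <- s_cand[order(cen, s_cand)][1]
    e <- s + P - 1L
    return(.pair_record(idx, s, e, idx$fwd_min[s], idx$rev_min[e]))
  }
  list(rejected = "NO_PRIMER",
       detail = "no product size in the amplicon range joins feasible primer windows")
}

#' Re-check a designed primer pair against its constraints
#'
#' Independent verification used by the test-suite and reporting layer:
#' recomputes length, GC, Tm and product-size constraints from the primer
#' sequences themselves.
#'
#' @param pair result of \code{\link{design_primers}}.
#' @param params the \code{\link{primer_params}} used.
#' @return TRUE when every constraint holds; otherwise a character vector
#'   naming the violated constraints.
#' @export
check_primer_pair <- function(pair, params = primer_params()) {
  if (!is.null(pair$rejected)) return("rejected")
  bad <- character(0)
  for (p in c("forward", "reverse")) {
    len <- nchar(pair[[p]])
    if (len < params$len_min || len > params$len_max)
      bad <- c(bad, paste0(p, "_length"))
    g <- gc_content(pair[[p]])
    if (g < params$gc_min || g > params$gc_max)
      bad <- c(bad, paste0(p, "_gc"))
    tm <- melting_temperature(pair[[p]])
    if (tm < params$tm_min || tm > params$tm_max)
      bad <- c(bad, paste0(p, "_tm"))
  }
  if (pair$product_size < params$amp_min || pair$product_size > params$amp_max)
    bad <- c(bad, "product_size")
  if (length(bad)) bad else TRUE
}
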