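## Genomic context of insertion loci: flanking GC content, gene density
## in a 2 Mb window, and recombination-rate context with per-arm means.

#' GC content of the flanking windows of an element
#'
#' 100 x (G+C)/(A+C+G+T) over the two `window`-bp windows flanking the
#' element (element sequence excluded); N and other ambiguity codes are
#' excluded from numerator and denominator. Windows are clipped at contig
#' ends.
#'
#' @param genome character scalar.
#' @param start,end element span, 0-based half-open.
#' @param window bp per side.
#' @return list(gc_percent, n_informative, flag).
#' @export
gc_content_flanks <- function(genome, start, end, window = 20000L) {
  L <- nchar(genome)
  up <- seq_slice(genome, max(0L, start - window), start)
  down <- seq_slice(genome, end, min(L, end + window))
  ch <- split_chars(paste0(up, down))
  gc <- sum(ch %in% c("G", "C"))
  at <- sum(ch %in% c("A", "T"))
  if (gc + at == 0L)
    return(list(gc_percent = NA_real_, n_informative = 0L,
                flag = "no unambiguous bases in windows"))
  list(gc_percent = 100 * gc / (gc + at), n_informative = gc + at,
       flag = "")
}

#' Gene density around an element
#'
#' Counts distinct genes overlapping (by at least 1 bp) a window of
#' `2 * half_window` bp centered on the element midpoint, divided by the
#' realized window length in Mb (clipped windows rescale the
#' denominator).
#'
#' @param genes data.frame(gene_id, start, end), 0-based half-open;
#'   duplicate `gene_id` rows count once.
#' @param start,end element span.
#' @param half_window bp.
#' @param contig_len contig length for clipping (Inf when unknown).
#' @return genes per Mb.
#' @export
gene_density <- function(genes, start, end, half_window = 1e6,
                         contig_len = Inf) {
  mid <- (start + end) / 2
  ws <- max(0, mid - half_window)
  we <- min(contig_len, mid + half_window)
  if (!nrow(genes)) return(0)
  ov <- genes$start < we & genes$end > ws
  n <- length(unique(genes$gene_id[ov]))
  n / ((we - ws) / 1e6)
}

#' Recombination-rate context of loci
#'
#' Per-locus rate is the rate of the window containing the element
#' midpoint; the summary reports arithmetic means overall and per
#' chromosome arm, rounded to 1 decimal.
#'
#' @param rate_windows data.frame(contig, start, end, rate), 0-based
#'   half-open tiles, rate in cM/Mb.
#' @param cytobands data.frame(contig, start, end, arm) with arm "p"/"q".
#' @param loci data.frame(locus_id, contig, start, end).
#' @return list(per_locus, summary) — per_locus has rate, arm and a flag
#'   for midpoints outside any window.
#' @export
recombination_context <- function(rate_windows, cytobands, loci) {
  n <- nrow(loci)
  rate <- rep(NA_real_, n); arm <- rep(NA_character_, n)
  flag <- character(n)
  for (i in seq_len(n)) {
    mid <- (loci$start[i] + loci$end[i]) %/% 2L
    w <- rate_windows[rate_windows$contig == loci$contig[i] &
                      rate_windows$start <= mid & rate_windows$end > mid, ,
                      drop = FALSE]
    if (nrow(w)) rate[i] <- w$rate[1]
    else flag[i] <- "midpoint outside rate windows"
    b <- cytobands[cytobands$contig == loci$contig[i] &
                   cytobands$start <= mid & cytobands$end > mid, ,
                   drop = FALSE]
    if (nrow(b)) arm[i] <- b$arm[1]
  }
  per_locus <- data.frame(locus_id = loci$locus_id, rate = rate, arm = arm,
                          flag = flag, stringsAsFactors = FALSE)
  mean1 <- function(x) round(mean(x, na.rm = TRUE), 1)
  summary <- data.frame(
    scope = c("all", "p", "q"),
    mean_rate = c(mean1(rate),
                  mean1(rate[arm == "p"]), mean1(rate[arm == "q"])),
    n = c(sum(!is.na(rate)),
          sum(!is.na(rate) & arm == "p"),
          sum(!is.na(rate) & arm == "q")),
    stringsAsFactors = FALSE)
  list(per_locus = per_locus, summary = summary)
}
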