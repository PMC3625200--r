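## Bundled toy provirus consensus.
##
## A deterministic ~9.5 kb stand-in for an ERV consensus: two identical
## 968 bp LTRs (the modal LTR length among the catalogued loci) around a
## 7,530 bp internal region carrying intact gag/pro/pol/env reading frames
## and a marked 292 bp pol-env boundary segment. The subtype-defining
## deletion of that segment leaves pol and env co-linear in one frame
## (pol length is a codon multiple), so the type I variant shows the
## in-frame pol-env fusion, while in the type II layout env sits 292 bp
## (i.e. +1 frame) downstream of pol. Sequence content is random but fixed;
## it is a synthetic consensus, not a transcription of any database entry.

.ervscribe_env <- new.env(parent = emptyenv())

LTR_LEN <- 968L
BOUNDARY_LEN <- 292L

random_codons <- function(n_codons) {
  codons <- as.vector(outer(
    as.vector(outer(BASES, BASES, paste0)), BASES, paste0))
  codons <- setdiff(codons, c("TAA", "TAG", "TGA"))
  paste(sample(codons, n_codons, replace = TRUE), collapse = "")
}

random_bases <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(BASES, n, replace = TRUE, prob = p), collapse = "")
}

#' Bundled toy provirus consensus
#'
#' Builds (once per session, deterministically) the synthetic provirus
#' consensus used by the simulator and as the default alignment reference:
#' 968 bp LTRs, a 7,530 bp internal region with intact, non-overlapping
#' gag/pro/pol/env ORFs, and a 292 bp pol-env boundary segment whose
#' presence/absence distinguishes subtype II from subtype I.
#'
#' @return a list with components:
#'   \item{seq}{full consensus sequence (LTR + internal + LTR), character.}
#'   \item{ltr}{the LTR sequence (both copies are identical).}
#'   \item{internal}{the internal (type II) sequence.}
#'   \item{internal_type1}{the internal sequence with the 292 bp boundary
#'     segment excised (type I).}
#'   \item{ltr5_span,internal_span,ltr3_span}{0-based half-open spans on
#'     `seq`.}
#'   \item{gene_map}{data.frame (gene, start, end, frame), 1-based inclusive
#'     coordinates on `seq`; frame 0 means translation starts at `start`.}
#'   \item{boundary_span}{1-based inclusive span of the 292 bp segment on
#'     `seq`.}
#' @export
toy_provirus <- function() {
  if (!is.null(.ervscribe_env$toy)) return(.ervscribe_env$toy)
  .ervscribe_env$toy <- with_seed(190813L, build_toy_provirus())
  .ervscribe_env$toy
}

build_toy_provirus <- function() {
  ltr <- random_bases(LTR_LEN, gc = 0.55)
  leader  <- random_bases(450L)
  gag     <- random_codons(656L)   # 1968 bp
  sp1     <- random_bases(42L)
  pro     <- random_codons(289L)   # 867 bp
  sp2     <- random_bases(33L)
  pol     <- random_codons(895L)   # 2685 bp, codon multiple: excising the
                                   # boundary fuses env into the pol frame
  boundary <- random_bases(BOUNDARY_LEN)
  env     <- random_codons(346L)   # 1038 bp
  trailer <- random_bases(155L)

  internal <- paste0(leader, gag, sp1, pro, sp2, pol, boundary, env, trailer)
  stopifnot(nchar(internal) == 7530L)
  seq <- paste0(ltr, internal, ltr)

  # 1-based inclusive gene spans on the full element
  off <- LTR_LEN
  pos <- function(i_start, len) c(off + i_start, off + i_start + len - 1L)
  g_gag <- pos(451L, 1968L)
  g_pro <- pos(2461L, 867L)
  g_pol <- pos(3361L, 2685L)
  g_bnd <- pos(6046L, BOUNDARY_LEN)
  g_env <- pos(6338L, 1038L)

  gene_map <- data.frame(
    gene  = c("gag", "pro", "pol", "env"),
    start = c(g_gag[1], g_pro[1], g_pol[1], g_env[1]),
    end   = c(g_gag[2], g_pro[2], g_pol[2], g_env[2]),
    frame = 0L,
    stringsAsFactors = FALSE
  )

  internal_type1 <- paste0(
    substr(internal, 1L, 6045L),
    substr(internal, 6045L + BOUNDARY_LEN + 1L, nchar(internal)))

  list(
    seq            = seq,
    ltr            = ltr,
    internal       = internal,
    internal_type1 = internal_type1,
    ltr5_span      = c(0L, LTR_LEN),
    internal_span  = c(LTR_LEN, LTR_LEN + 7530L),
    ltr3_span      = c(LTR_LEN + 7530L, LTR_LEN + 7530L + LTR_LEN),
    gene_map       = gene_map,
    boundary_span  = g_bnd
  )
}

#' Read / write a gene map TSV (gene, start, end, frame)
#'
#' Coordinates are 1-based inclusive on the consensus element.
#' @param path file path.
#' @export
read_gene_map <- function(path) {
  gm <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "start", "end", "frame")
  if (!all(need %in% names(gm)))
    stop("gene map must have columns: ", paste(need, collapse = ", "))
  gm[need]
}

#' @rdname read_gene_map
#' @param gene_map data.frame as returned by [toy_provirus()]`$gene_map`.
#' @export
write_gene_map <- function(gene_map, path) {
  utils::write.table(gene_map, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
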