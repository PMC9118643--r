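# Pairwise alignment wrappers and Karlin-Altschul significance.
#
# Local (Smith-Waterman) and global (Needleman-Wunsch) alignment are
# delegated to Biostrings::pairwiseAlignment, whose affine gap cost for a
# length-L gap is gapOpening + L * gapExtension, matching the BLAST
# convention used by the default parameters (BLOSUM62, 11/1 local, 10/0.5
# global).  The ambiguity letter X is allowed and scores 0 against
# everything.

# BLOSUM62 with a neutral (0) X row/column, cached per session
sod_submat <- function() {
  if (is.null(the_cache$submat)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    m <- e$BLOSUM62
    m["X", ] <- 0L
    m[, "X"] <- 0L
    the_cache$submat <- m
  }
  the_cache$submat
}

check_aa <- function(...) {
  seqs <- c(...)
  if (any(!nzchar(seqs))) stop("empty sequence")
  bad <- !.aa_ok(toupper(seqs))
  if (any(bad)) stop("non-amino-acid characters in sequence")
  invisible(toupper(seqs))
}

as_alignment <- function(pa) {
  list(score = score(pa),
       q_start = start(pattern(pa)), q_end = end(pattern(pa)),
       t_start = start(subject(pa)), t_end = end(subject(pa)),
       q_aln = as.character(pattern(pa)),
       t_aln = as.character(subject(pa)))
}

#' Optimal local (Smith-Waterman) alignment
#'
#' @param query,target Amino-acid strings (20 standard letters plus X;
#'   X scores 0 against everything).
#' @param gap_open,gap_ext Affine gap parameters; a length-L gap costs
#'   `gap_open + L * gap_ext`.
#' @param submat Substitution matrix (default BLOSUM62 with neutral X).
#' @return A list with `score`, 1-based inclusive spans `q_start`,
#'   `q_end`, `t_start`, `t_end`, and the aligned strings `q_aln`,
#'   `t_aln` (gaps as `-`).
#' @export
#' @examples
#' local_align("HEAGAWGHEE", "PAWHEAE")$score
local_align <- function(query, target, gap_open = 11, gap_ext = 1,
                        submat = sod_submat()) {
  s <- check_aa(query, target)
  pa <- pairwiseAlignment(s[1], s[2], type = "local",
                          substitutionMatrix = submat,
                          gapOpening = gap_open, gapExtension = gap_ext)
  as_alignment(pa)
}

#' Optimal global (Needleman-Wunsch) alignment
#'
#' End gaps are penalised.  `type = "global-local"` aligns the whole
#' query into the best-matching region of the target (used to place short
#' peptides into a longer reference).
#'
#' @inheritParams local_align
#' @param type `"global"` or `"global-local"`.
#' @return As [local_align()].
#' @export
global_align <- function(query, target, gap_open = 10, gap_ext = 0.5,
                         submat = sod_submat(), type = "global") {
  s <- check_aa(query, target)
  pa <- pairwiseAlignment(s[1], s[2], type = type,
                          substitutionMatrix = submat,
                          gapOpening = gap_open, gapExtension = gap_ext)
  as_alignment(pa)
}

#' Karlin-Altschul E-value
#'
#' `E = K * m * n * exp(-lambda * score)` for raw alignment score
#' `score`, query length `m` and target length `n`.  The default
#' parameters are fixed gapped-BLOSUM62 constants; they are approximate
#' and deliberately not re-estimated per query.
#'
#' @param score Raw alignment score (>= 0).
#' @param m,n Query and target lengths (positive).
#' @param lambda,K Karlin-Altschul parameters.
#' @return The expected number of chance hits at this score or better.
#' @export
#' @examples
#' alignment_evalue(0, 100, 100)   # K * m * n
alignment_evalue <- function(score, m, n, lambda = 0.267, K = 0.041) {
  if (any(m <= 0) || any(n <= 0)) stop("sequence lengths must be positive")
  if (any(score < 0)) stop("score must be non-negative")
  K * m * n * exp(-lambda * score)
}

# column statistics of an alignment: aligned columns (both non-gap),
# identical columns, BLOSUM-positive columns
aln_column_stats <- function(aln, submat = sod_submat()) {
  q <- strsplit(aln$q_aln, "")[[1]]
  t <- strsplit(aln$t_aln, "")[[1]]
  both <- q != "-" & t != "-"
  qq <- q[both]; tt <- t[both]
  n_aligned <- sum(both)
  n_ident <- sum(qq == tt)
  n_pos <- if (n_aligned > 0) sum(submat[cbind(qq, tt)] > 0) else 0L
  list(n_aligned = n_aligned, n_identical = n_ident, n_positive = n_pos,
       identity = if (n_aligned > 0) n_ident / n_aligned else NA_real_,
       positive = if (n_aligned > 0) n_pos / n_aligned else NA_real_)
}
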