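# Motif models (position weight matrices), motif-combination strings,
# promoter extraction and promoter scanning.
#
# De-novo motif discovery is out of scope: models are built from
# user-supplied instance sets (pwm_from_instances) or provided directly.
# Scanning reports best non-overlapping matches per model at a score
# threshold expressed as a fraction of the model's maximum score.

.dna_letters <- c("A", "C", "G", "T")

#' Build a motif model from aligned instances
#'
#' Column counts plus a pseudocount, normalised and converted to
#' log2-odds against the background.
#'
#' @param instances Character vector of >= 2 equal-length strings
#'   (protein or DNA alphabet, auto-detected unless given).
#' @param pseudocount Added to every count (default 0.1).
#' @param background Named background frequency vector over the
#'   alphabet; default uniform.
#' @param motif_id Identifier stored in the model (default `"1"`).
#' @param alphabet `"auto"`, `"protein"` or `"dna"`.
#' @return A list of class `motif_model`: `motif_id`, `pwm` (position x
#'   letter log2-odds), `consensus`, `background`, `alphabet`.
#' @export
pwm_from_instances <- function(instances, pseudocount = 0.1,
                               background = NULL, motif_id = "1",
                               alphabet = c("auto", "protein", "dna")) {
  alphabet <- match.arg(alphabet)
  if (length(instances) < 2) stop("need at least 2 instances")
  instances <- toupper(instances)
  L <- unique(nchar(instances))
  if (length(L) != 1) stop("instances must have equal lengths")
  if (alphabet == "auto")
    alphabet <- if (all(grepl("^[ACGT]+$", instances))) "dna" else "protein"
  letters <- if (alphabet == "dna") .dna_letters else .aa_letters
  if (is.null(background))
    background <- setNames(rep(1 / length(letters), length(letters)), letters)
  ch <- do.call(rbind, strsplit(instances, ""))
  if (any(!ch %in% letters)) stop("instance letters outside the ", alphabet, " alphabet")
  counts <- t(vapply(seq_len(L), function(j)
    table(factor(ch[, j], levels = letters)) + pseudocount,
    numeric(length(letters))))
  probs <- counts / rowSums(counts)
  pwm <- log2(sweep(probs, 2, background[letters], "/"))
  consensus <- paste(letters[max.col(probs, ties.method = "first")], collapse = "")
  structure(list(motif_id = as.character(motif_id), pwm = pwm,
                 consensus = consensus, background = background,
                 alphabet = alphabet),
            class = "motif_model")
}

# score every window start of seq under a pwm; letters outside the
# alphabet (e.g. X, N) contribute 0
pwm_scores <- function(seq, model) {
  ch <- strsplit(toupper(seq), "")[[1]]
  L <- nrow(model$pwm)
  n <- length(ch) - L + 1L
  if (n < 1) return(numeric(0))
  idx <- match(ch, colnames(model$pwm))
  vapply(seq_len(n), function(s) {
    cols <- idx[s:(s + L - 1L)]
    sum(model$pwm[cbind(which(!is.na(cols)), cols[!is.na(cols)])])
  }, numeric(1))
}

# greedy non-overlapping matches >= threshold, best score first, ties
# leftmost
.greedy_matches <- function(scores, L, thr) {
  cand <- which(scores >= thr)
  if (length(cand) == 0) return(data.frame(start = integer(), score = numeric()))
  cand <- cand[order(-scores[cand], cand)]
  taken <- logical(length(scores) + L)
  keep <- integer(0)
  for (s in cand) {
    span <- s:(s + L - 1L)
    if (!any(taken[span])) { keep <- c(keep, s); taken[span] <- TRUE }
  }
  keep <- sort(keep)
  data.frame(start = keep, score = scores[keep])
}

#' Scan a sequence with motif models
#'
#' Reports, per model, the best non-overlapping matches scoring at least
#' `score_fraction` of the model's maximum achievable score, and builds
#' the motif-combination string from the positional order of all
#' matches (e.g. `"1-3-2"`).
#'
#' @param seq Sequence string (alphabet must suit the models).
#' @param models List of `motif_model`s.
#' @param score_fraction Threshold in (0, 1] as a fraction of the
#'   maximum score.
#' @param id Sequence identifier for the output.
#' @return A list with `matches` (`data.frame`: `protein_id`,
#'   `motif_id`, `start`, `end` 1-based inclusive, `score`) and
#'   `combination` (dash-joined motif ids in positional order; `""` if
#'   none).
#' @export
scan_motifs <- function(seq, models, score_fraction = 0.8, id = "query") {
  if (score_fraction <= 0 || score_fraction > 1)
    stop("score_fraction must be in (0, 1]")
  out <- list()
  for (model in models) {
    L <- nrow(model$pwm)
    scores <- pwm_scores(seq, model)
    thr <- score_fraction * sum(apply(model$pwm, 1, max))
    m <- .greedy_matches(scores, L, thr)
    if (nrow(m) > 0)
      out[[length(out) + 1L]] <- data.frame(
        protein_id = id, motif_id = model$motif_id, start = m$start,
        end = m$start + L - 1L, score = m$score, stringsAsFactors = FALSE)
  }
  matches <- if (length(out)) do.call(rbind, out) else
    data.frame(protein_id = character(), motif_id = character(),
               start = integer(), end = integer(), score = numeric())
  matches <- matches[order(matches$start, matches$motif_id), , drop = FALSE]
  rownames(matches) <- NULL
  list(matches = matches,
       combination = paste(matches$motif_id, collapse = "-"))
}

#' Extract promoter regions upstream of gene 5' ends
#'
#' For a `+` strand gene the promoter is the `length` bases ending just
#' before `start`; for a `-` strand gene, the `length` bases starting
#' just after `end`, reverse-complemented.  Regions truncated at the
#' contig edge are flagged.  The anchor is the gene feature 5' end (the
#' translation start when gene models are CDS-anchored).
#'
#' @param genome A named `DNAStringSet` (or named character vector).
#' @param loci Locus `data.frame` (see [read_gff3()]).
#' @param length Promoter length in bp (default 2000).
#' @return A `data.frame`: `gene_id`, `chrom`, `start`, `end` (1-based
#'   inclusive, genome coordinates of the extracted window), `strand`,
#'   `seq` (strand-corrected), `truncated`.
#' @export
extract_promoters <- function(genome, loci, length = 2000L) {
  if (is.character(genome)) genome <- DNAStringSet(genome)
  missing <- setdiff(unique(loci$chrom), names(genome))
  if (base::length(missing) > 0)
    stop("chromosomes absent from genome: ", paste(missing, collapse = ", "))
  rows <- lapply(seq_len(nrow(loci)), function(i) {
    chrom <- loci$chrom[i]
    clen <- width(genome[chrom])
    if (loci$strand[i] == "+") {
      e <- loci$start[i] - 1L
      s <- max(1L, loci$start[i] - length)
      truncated <- s > loci$start[i] - length || e < 1L
      seq <- if (e >= s) as.character(subseq(genome[[chrom]], s, e)) else ""
    } else {
      s <- loci$end[i] + 1L
      e <- min(clen, loci$end[i] + length)
      truncated <- e < loci$end[i] + length || s > clen
      seq <- if (e >= s)
        as.character(reverseComplement(subseq(genome[[chrom]], s, e))) else ""
    }
    data.frame(gene_id = loci$gene_id[i], chrom = chrom,
               start = if (e >= s) s else NA_integer_,
               end = if (e >= s) e else NA_integer_,
               strand = loci$strand[i], seq = seq, truncated = truncated,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Scan promoters with DNA motif models on both strands
#'
#' Each promoter is scanned forward and as its reverse complement; a
#' palindromic site therefore contributes one match on each strand.
#' Counts are reported per model and, when a `families` map is given,
#' aggregated per user-assigned family.
#'
#' @param promoters `data.frame` from [extract_promoters()] (fields
#'   `gene_id`, `seq`).
#' @param models List of DNA `motif_model`s.
#' @param score_fraction Threshold as in [scan_motifs()].
#' @param families Optional named character vector mapping `motif_id` to
#'   a family label.
#' @return A list with `counts` (`data.frame`: `gene_id`, `motif_id`,
#'   `n_hits`) and, if `families` is given, `family_counts`.
#' @export
scan_promoters <- function(promoters, models, score_fraction = 0.8,
                           families = NULL) {
  if (any(vapply(models, function(m) m$alphabet, character(1)) != "dna"))
    stop("promoter scanning requires DNA motif models")
  rows <- list()
  for (i in seq_len(nrow(promoters))) {
    seq <- promoters$seq[i]
    rc <- as.character(reverseComplement(DNAStringSet(seq))[[1]])
    for (model in models) {
      n <- nrow(scan_motifs(seq, list(model), score_fraction)$matches) +
           nrow(scan_motifs(rc,  list(model), score_fraction)$matches)
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = promoters$gene_id[i], motif_id = model$motif_id,
        n_hits = n, stringsAsFactors = FALSE)
    }
  }
  counts <- do.call(rbind, rows)
  out <- list(counts = counts)
  if (!is.null(families)) {
    counts$family <- families[counts$motif_id]
    agg <- stats::aggregate(n_hits ~ gene_id + family, counts, sum)
    out$family_counts <- agg[order(agg$gene_id, agg$family), , drop = FALSE]
  }
  out
}
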