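# FASTA / GFF3 / TSV input-output and run configuration.

.aa_ok <- function(seqs) grepl("^[ACDEFGHIKLMNPQRSTVWYX]+$", seqs)

# coerce protein input (AAStringSet, named character) to named character
as_protein_set <- function(x, what = "proteins") {
  if (is(x, "AAStringSet")) x <- setNames(as.character(x), names(x))
  if (!is.character(x)) stop(what, " must be an AAStringSet or named character vector")
  if (is.null(names(x)) || any(names(x) == ""))
    stop(what, " must be named by protein id")
  x <- toupper(x)
  bad <- !.aa_ok(x)
  if (any(bad))
    stop("invalid amino-acid letters in: ", paste(names(x)[bad], collapse = ", "))
  if (anyDuplicated(names(x)))
    stop("duplicate protein ids: ",
         paste(unique(names(x)[duplicated(names(x))]), collapse = ", "))
  x
}

#' Read a FASTA file
#'
#' Reads protein or nucleotide FASTA into a `Biostrings` string set.
#' Sequences are upper-cased; duplicate identifiers and empty files are
#' errors.  The identifier is the first whitespace-delimited token of the
#' header.
#'
#' @param path Path to a FASTA file.
#' @param type `"protein"` (default) or `"dna"`.
#' @return An [Biostrings::AAStringSet] or [Biostrings::DNAStringSet]
#'   named by record id.
#' @export
read_fasta <- function(path, type = c("protein", "dna")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("file not found: ", path)
  set <- if (type == "protein") readAAStringSet(path) else readDNAStringSet(path)
  if (length(set) == 0) stop("empty FASTA file: ", path)
  names(set) <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(names(set)))
    stop("duplicate FASTA ids: ",
         paste(unique(names(set)[duplicated(names(set))]), collapse = ", "))
  if (type == "protein") {
    set <- AAStringSet(toupper(as.character(set)))
  } else {
    set <- DNAStringSet(toupper(as.character(set)))
  }
  set
}

#' Write a FASTA file
#'
#' @param x A named `XStringSet` or named character vector of sequences.
#' @param path Output path.
#' @param type `"protein"` or `"dna"` (used when `x` is character).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, type = c("protein", "dna")) {
  type <- match.arg(type)
  if (is.character(x))
    x <- if (type == "protein") AAStringSet(x) else DNAStringSet(x)
  writeXStringSet(x, path)
  invisible(path)
}

#' Read gene loci from a GFF3 file
#'
#' Parses `gene` features (column 3 == `"gene"`) of a GFF3 file into a
#' gene-locus table.  Coordinates stay 1-based inclusive, the native GFF3
#' and R/Bioconductor convention.  Genes are sorted within each
#' chromosome by start (ties broken by end, then id) and assigned a dense
#' `rank` 1..n per chromosome; the rank ordering is what the tandem rule
#' counts intervening genes on.
#'
#' @param path Path to a GFF3 file.
#' @return A `data.frame` with columns `gene_id`, `chrom`, `start`,
#'   `end`, `strand`, `rank`.
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) stop("no feature lines in GFF3: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9))
    stop("malformed GFF3 (expected 9 columns) at line ",
         lineno[which(nf != 9)[1]])
  m <- do.call(rbind, fields)
  gene <- m[, 3] == "gene"
  if (!any(gene)) stop("no gene features in GFF3: ", path)
  m <- m[gene, , drop = FALSE]
  lineno <- lineno[gene]
  start <- suppressWarnings(as.integer(m[, 4]))
  end <- suppressWarnings(as.integer(m[, 5]))
  if (anyNA(start) || anyNA(end))
    stop("non-numeric coordinate at line ",
         lineno[which(is.na(start) | is.na(end))[1]])
  if (any(start > end))
    stop("start > end at line ", lineno[which(start > end)[1]])
  strand <- m[, 7]
  if (any(!strand %in% c("+", "-")))
    stop("unknown strand symbol at line ",
         lineno[which(!strand %in% c("+", "-"))[1]])
  id <- sub(".*ID=([^;]+).*", "\\1", m[, 9])
  noid <- !grepl("ID=", m[, 9])
  if (any(noid)) id[noid] <- paste0("gene_", seq_len(sum(noid)))
  loci <- data.frame(gene_id = id, chrom = m[, 1], start = start,
                     end = end, strand = strand, stringsAsFactors = FALSE)
  rank_loci(loci)
}

#' @rdname read_gff3
#' @param loci A locus `data.frame` (columns `gene_id`, `chrom`, `start`,
#'   `end`, `strand`) to re-rank.
#' @export
rank_loci <- function(loci) {
  ord <- order(loci$chrom, loci$start, loci$end, loci$gene_id)
  loci <- loci[ord, , drop = FALSE]
  loci$rank <- stats::ave(loci$start, loci$chrom,
                          FUN = seq_along)
  loci$rank <- as.integer(loci$rank)
  rownames(loci) <- NULL
  loci
}

#' Write gene loci as GFF3
#'
#' @param loci Locus `data.frame` as returned by [read_gff3()].
#' @param path Output path.
#' @param source Value for the GFF3 source column.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(loci, path, source = "sodscan") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  writeLines(sprintf("%s\t%s\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     loci$chrom, source, loci$start, loci$end,
                     loci$strand, loci$gene_id), con)
  invisible(path)
}

#' Pipeline run configuration
#'
#' Defaults follow the study design this pipeline implements: candidate
#' hits at E-value <= 1e-10; duplicates require coverage and identity
#' both above 70%; tandem arrays allow at most 5 intervening genes within
#' a 100-kb window; promoters are the 2000 bp upstream of the gene 5'
#' end; the ANOVA significance level is 0.05.
#'
#' @param evalue_threshold E-value cutoff for domain hits.
#' @param dup_coverage Minimum aligned coverage fraction (of the longer
#'   sequence) for a duplicate pair; strict inequality.
#' @param dup_identity Minimum aligned-column identity fraction; strict
#'   inequality.
#' @param tandem_max_intervening Maximum number of genes between tandem
#'   neighbours.
#' @param tandem_window_bp Maximum genomic span (bp) of a tandem array.
#' @param promoter_len_bp Promoter length upstream of the gene 5' end.
#' @param anova_alpha Significance level for response calls.
#' @param rng_seed Seed used by any stochastic stage.
#' @param min_protein_len Minimum protein length (aa) retained by the
#'   scan stage (partial coding sequences are filtered).
#' @param similarity_mode `"identity"` (default) or `"positive"`
#'   (BLOSUM62-positive fraction) for the 70/70 duplicate rule.
#' @param min_block Minimum number of anchor pairs in a collinear block.
#' @param longest_isoform Collapse multiple isoforms per locus to the
#'   longest before counting candidates (applies when a protein-to-locus
#'   map carries several proteins per gene).
#' @return A list of class `sod_config`.
#' @export
sod_config <- function(evalue_threshold = 1e-10,
                       dup_coverage = 0.70,
                       dup_identity = 0.70,
                       tandem_max_intervening = 5L,
                       tandem_window_bp = 100000L,
                       promoter_len_bp = 2000L,
                       anova_alpha = 0.05,
                       rng_seed = 1L,
                       min_protein_len = 100L,
                       similarity_mode = c("identity", "positive"),
                       min_block = 3L,
                       longest_isoform = TRUE) {
  similarity_mode <- match.arg(similarity_mode)
  stopifnot(evalue_threshold > 0,
            dup_coverage >= 0, dup_coverage <= 1,
            dup_identity >= 0, dup_identity <= 1,
            tandem_max_intervening >= 0, tandem_window_bp > 0,
            promoter_len_bp > 0, anova_alpha > 0, anova_alpha < 1)
  structure(list(evalue_threshold = evalue_threshold,
                 dup_coverage = dup_coverage,
                 dup_identity = dup_identity,
                 tandem_max_intervening = as.integer(tandem_max_intervening),
                 tandem_window_bp = as.integer(tandem_window_bp),
                 promoter_len_bp = as.integer(promoter_len_bp),
                 anova_alpha = anova_alpha,
                 rng_seed = as.integer(rng_seed),
                 min_protein_len = as.integer(min_protein_len),
                 similarity_mode = similarity_mode,
                 min_block = as.integer(min_block),
                 longest_isoform = isTRUE(longest_isoform)),
            class = "sod_config")
}

# uniform TSV writers: deterministic, tab-separated, no quoting
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, ...)
}
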