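# Top-level orchestration: scan -> physchem -> classify -> genome
# context -> expression, writing TSV tables and a structured log.

log_line <- function(con, stage, msg) {
  writeLines(sprintf("[%s] %s", stage, msg), con)
}

run_stage <- function(stage, con, expr) {
  log_line(con, stage, "start")
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full SOD gene-family pipeline
#'
#' Executes the identification, profiling, classification, genome
#' context and (when count data are provided) expression stages over
#' the supplied inputs, writing one TSV per stage plus a structured log
#' into `out_dir`.  Outputs are a pure function of (inputs, config,
#' seed): the same inputs and configuration reproduce the same bytes.
#'
#' @param config A [sod_config()].
#' @param proteins_fasta Protein FASTA path (required).
#' @param gff3 Gene-model GFF3 path (required).
#' @param genome_fasta Optional genome FASTA (enables promoter
#'   extraction).
#' @param counts_tsv,design_tsv,lengths_tsv Optional expression inputs:
#'   a gene x sample count table (first column gene id), a
#'   `sample`/`condition` design and a `gene_id`/`length_bp` table.
#' @param control Control condition for response calls (required when
#'   counts are given).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list of the per-stage results.
#' @export
run_pipeline <- function(config = sod_config(), proteins_fasta, gff3,
                         genome_fasta = NULL, counts_tsv = NULL,
                         design_tsv = NULL, lengths_tsv = NULL,
                         control = NULL, out_dir = "sodscan_out") {
  inputs <- c(proteins_fasta, gff3, genome_fasta, counts_tsv, design_tsv,
              lengths_tsv)
  missing <- inputs[!file.exists(inputs)]
  if (length(missing) > 0)
    stop("missing input file(s): ", paste(missing, collapse = ", "))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  con <- file(file.path(out_dir, "sodscan.log"), "w")
  on.exit(close(con))
  log_line(con, "config",
           paste(names(unclass(config)), unlist(config), sep = "=",
                 collapse = " "))
  set.seed(config$rng_seed)

  proteins <- run_stage("read", con, read_fasta(proteins_fasta))
  loci <- run_stage("read", con, read_gff3(gff3))

  scan <- run_stage("scan", con, scan_proteome(proteins, config))
  write_tsv(merge(scan$architectures,
                  hits_to_bed(scan$hits), by = "protein_id", all.x = TRUE),
            file.path(out_dir, "candidates.tsv"))
  log_line(con, "scan", sprintf("%d candidates of %d proteins",
                                length(scan$candidates), length(proteins)))

  cand <- as_protein_set(proteins)[scan$candidates]
  phys <- run_stage("physchem", con, physchem_profile(cand))
  write_tsv(phys, file.path(out_dir, "physchem.tsv"))

  cls <- run_stage("classify", con, classify_proteome(scan, proteins))
  write_tsv(cls, file.path(out_dir, "classification.tsv"))
  prof <- attr(cls, "profiles")
  if (!is.null(prof)) write_tsv(prof, file.path(out_dir, "ligand_profiles.tsv"))

  ctx <- run_stage("context", con, {
    cand_with_loci <- cand[names(cand) %in% loci$gene_id]
    dp <- duplicate_pairs(cand_with_loci, loci, config)
    ta <- tandem_arrays(dp, loci, config)
    list(dup_pairs = dp, tandem = ta)
  })
  write_tsv(ctx$dup_pairs, file.path(out_dir, "duplication.tsv"))
  write_tsv(ctx$tandem, file.path(out_dir, "tandem_arrays.tsv"))

  promoters <- NULL
  if (!is.null(genome_fasta)) {
    promoters <- run_stage("promoters", con, {
      genome <- read_fasta(genome_fasta, type = "dna")
      extract_promoters(genome, loci[loci$gene_id %in% names(cand), ],
                        config$promoter_len_bp)
    })
    write_tsv(promoters[, setdiff(names(promoters), "seq")],
              file.path(out_dir, "promoters.tsv"))
  }

  calls <- NULL
  if (!is.null(counts_tsv)) {
    if (is.null(design_tsv) || is.null(lengths_tsv) || is.null(control))
      stop("expression stage needs counts, design, lengths and a control condition")
    calls <- run_stage("express", con, {
      cts <- read_tsv(counts_tsv, row.names = 1)
      design <- read_tsv(design_tsv)
      lens <- read_tsv(lengths_tsv)
      em <- expression_matrix(as.matrix(cts),
                              lens$length_bp[match(rownames(cts), lens$gene_id)],
                              design)
      ab <- tpm(em)
      calls <- anova_duncan(ab, design, control, alpha = config$anova_alpha)
      write_tsv(data.frame(gene_id = rownames(ab), round(ab, 4)),
                file.path(out_dir, "abundance_tpm.tsv"))
      calls
    })
    write_tsv(calls, file.path(out_dir, "expression_calls.tsv"))
  }

  log_line(con, "done", "all stages complete")
  invisible(list(scan = scan, physchem = phys, classification = cls,
                 context = ctx, promoters = promoters, calls = calls))
}
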