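# Candidate identification by iterative best-hit-then-mask domain
# scanning against the embedded reference registry.

#' Scan a protein for SOD domains
#'
#' Finds the best local alignment of every reference domain against the
#' still-unmasked parts of the protein; if its E-value passes the
#' threshold the span is recorded as a hit and masked (later hits may
#' not overlap earlier ones at all), and the search repeats.  Ties in
#' E-value are broken by registry order.  A hit must cover at least
#' `min_hit_len` alignment columns, which suppresses spurious micro-hits
#' after masking.
#'
#' The family call is `MnFe_family` if any `SOD_FE_*` hit was recorded,
#' else `CuZn_family` if any `SOD_CU` hit, else `none`; `n_sod_cu`
#' counts `SOD_CU` hits (multi-domain Cu/Zn proteins carry up to 4).
#'
#' @param protein A single amino-acid string, or a length-1 named
#'   character vector / `AAStringSet` element.
#' @param id Protein identifier used in the output (defaults to the name
#'   of `protein`, or `"query"`).
#' @param registry Reference registry, see [sod_domain_registry()].
#' @param evalue_threshold Maximum E-value of a reportable hit.
#' @param min_hit_len Minimum number of alignment columns in a hit.
#' @return A list with elements `architecture` (a one-row `data.frame`
#'   with `protein_id`, `ordered_domains` (dash-joined), `n_sod_cu`,
#'   `family_call`) and `hits` (a `data.frame` with `protein_id`,
#'   `domain_name`, `start`, `end` (1-based inclusive on the protein),
#'   `score`, `evalue`).
#' @export
scan_domains <- function(protein, id = NULL,
                         registry = sod_domain_registry(),
                         evalue_threshold = 1e-10, min_hit_len = 40L) {
  if (length(registry) == 0) stop("empty reference registry")
  if (is(protein, "AAStringSet")) protein <- setNames(as.character(protein), names(protein))
  if (is.null(id)) id <- if (!is.null(names(protein))) names(protein)[1] else "query"
  seq <- check_aa(unname(protein[1]))
  n <- nchar(seq)

  segments <- data.frame(s = 1L, e = n)
  hits <- list()
  repeat {
    best <- NULL
    for (ref in registry) {
      m <- nchar(ref$seq)
      for (k in seq_len(nrow(segments))) {
        s0 <- segments$s[k]; e0 <- segments$e[k]
        if (e0 - s0 + 1L < min_hit_len) next
        al <- local_align(ref$seq, substr(seq, s0, e0))
        if (al$score <= 0) next
        ev <- alignment_evalue(al$score, m = m, n = n)
        if (ev > evalue_threshold) next
        if (nchar(al$q_aln) < min_hit_len) next
        # strict '<' keeps the earliest registry entry on ties
        if (is.null(best) || ev < best$evalue) {
          best <- list(domain_name = ref$name,
                       start = s0 + al$t_start - 1L,
                       end = s0 + al$t_end - 1L,
                       score = al$score, evalue = ev, seg = k)
        }
      }
    }
    if (is.null(best)) break
    hits[[length(hits) + 1L]] <- best
    # split the segment around the masked span
    k <- best$seg
    s0 <- segments$s[k]; e0 <- segments$e[k]
    segments <- segments[-k, , drop = FALSE]
    if (best$start - s0 >= 1L)
      segments <- rbind(segments, data.frame(s = s0, e = best$start - 1L))
    if (e0 - best$end >= 1L)
      segments <- rbind(segments, data.frame(s = best$end + 1L, e = e0))
  }

  if (length(hits) > 0) {
    hits <- do.call(rbind, lapply(hits, function(h)
      data.frame(protein_id = id, domain_name = h$domain_name,
                 start = h$start, end = h$end, score = h$score,
                 evalue = h$evalue, stringsAsFactors = FALSE)))
    hits <- hits[order(hits$start), , drop = FALSE]
    rownames(hits) <- NULL
  } else {
    hits <- data.frame(protein_id = character(), domain_name = character(),
                       start = integer(), end = integer(),
                       score = numeric(), evalue = numeric())
  }
  n_cu <- sum(hits$domain_name == "SOD_CU")
  family <- if (any(grepl("^SOD_FE", hits$domain_name))) "MnFe_family"
            else if (n_cu > 0) "CuZn_family" else "none"
  arch <- data.frame(protein_id = id,
                     ordered_domains = paste(hits$domain_name, collapse = "-"),
                     n_sod_cu = n_cu, family_call = family,
                     stringsAsFactors = FALSE)
  list(architecture = arch, hits = hits)
}

#' Scan a protein collection for SOD candidates
#'
#' Applies [scan_domains()] to every record, after filtering proteins
#' shorter than `min_protein_len` (partial coding sequences).
#'
#' @param proteins An `AAStringSet` or named character vector.
#' @param config A [sod_config()].
#' @param registry Reference registry.
#' @return A list with `architectures` (one row per scanned protein),
#'   `hits` (all domain hits) and `candidates` (ids with a family call
#'   other than `none`).
#' @export
scan_proteome <- function(proteins, config = sod_config(),
                          registry = sod_domain_registry()) {
  prot <- as_protein_set(proteins)
  prot <- prot[nchar(prot) >= config$min_protein_len]
  res <- lapply(names(prot), function(id)
    scan_domains(prot[[id]], id = id, registry = registry,
                 evalue_threshold = config$evalue_threshold))
  arch <- do.call(rbind, lapply(res, `[[`, "architecture"))
  hits <- do.call(rbind, lapply(res, `[[`, "hits"))
  if (is.null(arch))
    arch <- data.frame(protein_id = character(), ordered_domains = character(),
                       n_sod_cu = integer(), family_call = character())
  list(architectures = arch, hits = hits,
       candidates = arch$protein_id[arch$family_call != "none"])
}

# convert 1-based inclusive hit coordinates to the 0-based half-open
# convention used in exported TSV tables
hits_to_bed <- function(hits) {
  out <- hits
  out$start <- out$start - 1L
  out
}
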