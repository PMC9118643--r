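# Expression normalisation (FPKM/TPM), log2 heat values, fold changes
# and response calling by one-way ANOVA followed by Duncan's multiple
# range test.

#' Construct an expression matrix object
#'
#' @param counts Non-negative integer matrix, genes x samples, with
#'   dimnames.
#' @param gene_length_bp Positive per-gene lengths, named or in row
#'   order.
#' @param design `data.frame` with columns `sample` and `condition`.
#' @param library_size Per-sample totals; defaults to column sums.
#' @return A list of class `expr_matrix`.
#' @export
expression_matrix <- function(counts, gene_length_bp, design,
                              library_size = colSums(counts)) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("negative counts")
  if (length(gene_length_bp) != nrow(counts))
    stop("gene_length_bp length mismatch")
  if (any(gene_length_bp <= 0)) stop("gene lengths must be positive")
  if (!all(c("sample", "condition") %in% names(design)))
    stop("design needs 'sample' and 'condition' columns")
  if (!setequal(design$sample, colnames(counts)))
    stop("design samples do not match count columns")
  design <- design[match(colnames(counts), design$sample), ]
  structure(list(counts = counts,
                 gene_length_bp = setNames(gene_length_bp, rownames(counts)),
                 design = design,
                 library_size = setNames(library_size, colnames(counts))),
            class = "expr_matrix")
}

#' Fragments per kilobase per million mapped (FPKM)
#'
#' `FPKM = counts * 1e9 / (library_size * gene_length)`.
#'
#' @param em An [expression_matrix()].
#' @return Gene x sample abundance matrix.
#' @export
fpkm <- function(em) {
  if (any(em$library_size <= 0))
    stop("zero library size for sample: ",
         paste(names(em$library_size)[em$library_size <= 0], collapse = ", "))
  sweep(sweep(em$counts * 1e9, 2, em$library_size, "/"),
        1, em$gene_length_bp, "/")
}

#' Transcripts per million (TPM)
#'
#' Length-normalised rates rescaled so every sample column sums to 1e6.
#'
#' @param em An [expression_matrix()].
#' @return Gene x sample abundance matrix with columns summing to 1e6.
#' @export
tpm <- function(em) {
  rate <- sweep(em$counts, 1, em$gene_length_bp, "/")
  denom <- colSums(rate)
  if (any(denom == 0))
    stop("all-zero sample column: ",
         paste(colnames(em$counts)[denom == 0], collapse = ", "))
  sweep(rate, 2, denom, "/") * 1e6
}

#' Log2 heat-map values
#'
#' @param abundance Non-negative abundance matrix.
#' @param pseudo Pseudo-count added before log2 (default 1).
#' @return `log2(abundance + pseudo)`.
#' @export
heat_values <- function(abundance, pseudo = 1) {
  if (any(abundance < 0)) stop("negative abundance")
  log2(abundance + pseudo)
}

#' Per-condition fold changes against a control
#'
#' `(mean_condition + pseudo) / (mean_control + pseudo)` on the
#' abundance scale.
#'
#' @param abundance Gene x sample abundance matrix.
#' @param design `data.frame` with `sample`, `condition`.
#' @param control Name of the control condition.
#' @param pseudo Pseudo-count (default 1).
#' @return Gene x condition matrix of ratios (control column included,
#'   identically 1).
#' @export
fold_change <- function(abundance, design, control, pseudo = 1) {
  if (!control %in% design$condition) stop("control condition not in design")
  conds <- unique(design$condition)
  means <- vapply(conds, function(cc)
    rowMeans(abundance[, design$sample[design$condition == cc], drop = FALSE]),
    numeric(nrow(abundance)))
  if (nrow(abundance) == 1L)
    means <- matrix(means, nrow = 1,
                    dimnames = list(rownames(abundance), conds))
  (means + pseudo) / (means[, control] + pseudo)
}

# Duncan critical ranges for spans 2..k: the studentized-range quantile
# at the stepwise protection level alpha_p = 1 - (1 - alpha)^(p - 1),
# scaled by sqrt(MSE / n_h)
duncan_ranges <- function(k, df_error, alpha, mse, n_h) {
  p <- 2:k
  q <- qtukey((1 - alpha)^(p - 1), p, df_error)
  setNames(c(NA_real_, q * sqrt(mse / n_h)), as.character(1:k))
}

# Duncan multiple range test on sorted means: returns letter display.
# means: named, sorted decreasing.  ranges: critical range per span.
duncan_letters <- function(means, ranges) {
  k <- length(means)
  if (k == 1) return(setNames("a", names(means)))
  homog <- matrix(FALSE, k, k)
  # recursive shortest significant ranges with the containment rule
  stack <- list(c(1L, k))
  seen <- new.env()
  while (length(stack) > 0) {
    iv <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- iv[1]; j <- iv[2]
    key <- paste(i, j)
    if (!is.null(seen[[key]]) || j <= i) next
    seen[[key]] <- TRUE
    if (means[i] - means[j] <= ranges[as.character(j - i + 1L)]) {
      homog[i, j] <- TRUE
    } else {
      stack[[length(stack) + 1L]] <- c(i, j - 1L)
      stack[[length(stack) + 1L]] <- c(i + 1L, j)
    }
  }
  # maximal homogeneous intervals (plus singletons for uncovered means)
  ivs <- which(homog, arr.ind = TRUE)
  ivs <- ivs[order(ivs[, 1], -ivs[, 2]), , drop = FALSE]
  keep <- list()
  for (r in seq_len(nrow(ivs))) {
    i <- ivs[r, 1]; j <- ivs[r, 2]
    contained <- any(vapply(keep, function(iv) iv[1] <= i && j <= iv[2],
                            logical(1)))
    if (!contained) keep[[length(keep) + 1L]] <- c(i, j)
  }
  covered <- rep(FALSE, k)
  for (iv in keep) covered[iv[1]:iv[2]] <- TRUE
  for (i in which(!covered)) keep[[length(keep) + 1L]] <- c(i, i)
  keep <- keep[order(vapply(keep, `[`, integer(1), 1))]
  letters_out <- rep("", k)
  for (li in seq_along(keep)) {
    iv <- keep[[li]]
    letters_out[iv[1]:iv[2]] <- paste0(letters_out[iv[1]:iv[2]], letters[li])
  }
  setNames(letters_out, names(means))
}

#' Response calls by one-way ANOVA and Duncan's multiple range test
#'
#' Per gene: a fixed-effects one-way ANOVA across conditions; when
#' `P < alpha`, Duncan's multiple range test assigns letter groups to
#' the condition means (conditions sharing a letter are not declared
#' different) and each condition is called `up` or `down` against the
#' control when the two share no letter.  Unequal group sizes use the
#' harmonic mean.  By default abundances are log2(x + 1) transformed
#' first (variance stabilisation on the heat-map scale).
#'
#' @param abundance Gene x sample abundance matrix.
#' @param design `data.frame` with `sample`, `condition`; every
#'   condition needs >= 2 replicates.
#' @param control Name of the control condition.
#' @param alpha Significance level (default 0.05).
#' @param log2_transform Transform abundances with `log2(x + 1)` before
#'   testing (default `TRUE`).
#' @return A `data.frame` with `gene_id`, `f_stat`, `p_value`,
#'   `significant`, one `letter.<condition>` column per condition and
#'   one `dir.<condition>` column (`up`/`down`/`none`) per non-control
#'   condition.
#' @export
anova_duncan <- function(abundance, design, control, alpha = 0.05,
                         log2_transform = TRUE) {
  if (!control %in% design$condition) stop("control condition not in design")
  design <- design[match(colnames(abundance), design$sample), ]
  cond <- factor(design$condition)
  sizes <- table(cond)
  if (any(sizes < 2))
    stop("conditions with fewer than 2 replicates: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  x <- if (log2_transform) heat_values(abundance) else abundance
  k <- nlevels(cond)
  n <- ncol(x)
  df_error <- n - k
  n_h <- k / sum(1 / sizes)
  conds <- levels(cond)
  rows <- vector("list", nrow(x))
  for (g in seq_len(nrow(x))) {
    y <- x[g, ]
    if (max(y) - min(y) == 0) {
      f <- 0; p <- 1
    } else {
      ow <- stats::oneway.test(y ~ cond, var.equal = TRUE)
      f <- unname(ow$statistic); p <- unname(ow$p.value)
      if (is.na(f)) { f <- 0; p <- 1 }
    }
    means <- tapply(y, cond, mean)
    mse <- sum((y - means[as.character(cond)])^2) / df_error
    letters_g <- if (p < alpha) {
      srt <- sort(means, decreasing = TRUE)
      duncan_letters(srt, duncan_ranges(k, df_error, alpha, mse, n_h))[conds]
    } else setNames(rep("a", k), conds)
    dir_g <- vapply(setdiff(conds, control), function(cc) {
      shared <- any(strsplit(letters_g[[cc]], "")[[1]] %in%
                    strsplit(letters_g[[control]], "")[[1]])
      if (p < alpha && !shared) {
        if (means[[cc]] > means[[control]]) "up" else "down"
      } else "none"
    }, character(1))
    row <- data.frame(gene_id = rownames(x)[g], f_stat = f, p_value = p,
                      significant = p < alpha, stringsAsFactors = FALSE)
    for (cc in conds) row[[paste0("letter.", cc)]] <- letters_g[[cc]]
    for (cc in names(dir_g)) row[[paste0("dir.", cc)]] <- dir_g[[cc]]
    rows[[g]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
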