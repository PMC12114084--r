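# Reading, validating and writing GWAS summary-statistic tables and the
# pipeline's result tables.

.SUMSTAT_FIELDS <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
                     "eaf", "beta", "se", "pvalue", "n")
.MANDATORY_FIELDS <- setdiff(.SUMSTAT_FIELDS, "eaf")
.VALID_ALLELES <- c("A", "C", "G", "T")

#' Default column mapping for summary-statistic files
#'
#' Maps each canonical field name to itself. Supply a modified copy to
#' [read_sumstats()] when a file uses different headers.
#'
#' @return Named character vector mapping canonical field -> column name.
#' @export
#' @examples
#' default_column_map()
default_column_map <- function() {
  stats::setNames(.SUMSTAT_FIELDS, .SUMSTAT_FIELDS)
}

#' Read a column mapping from a YAML or JSON key-value file
#'
#' @param path File whose extension decides the parser (`.yaml`/`.yml` or
#'   `.json`). Keys are canonical field names, values the file's column
#'   headers.
#' @return Named character vector usable as `column_map`.
#' @export
read_column_map <- function(path) {
  ext <- tolower(tools::file_ext(path))
  m <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the 'yaml' package is required to read YAML column maps", call. = FALSE)
    }
    yaml::read_yaml(path)
  } else if (ext == "json") {
    if (!requireNamespace("jsonlite", quietly = TRUE)) {
      stop("the 'jsonlite' package is required to read JSON column maps", call. = FALSE)
    }
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("column map must be a .yaml/.yml or .json file", call. = FALSE)
  }
  unlist(m)
}

# Row-level validation. Returns a logical keep mask plus a reason table;
# never mutates values of surviving rows (alleles are upper-cased before
# validation, which is part of normalisation, not validation).
validate_rows <- function(df) {
  n_row <- nrow(df)
  reason <- rep(NA_character_, n_row)
  flag <- function(bad, why) {
    bad[is.na(bad)] <- TRUE
    reason[bad & is.na(reason)] <<- why
  }
  flag(is.na(df$snp_id) | df$snp_id == "", "missing snp_id")
  flag(is.na(df$chrom) | df$chrom == "", "missing chrom")
  flag(!is.finite(df$pos) | df$pos < 1 | df$pos != round(df$pos), "invalid pos")
  flag(!(df$effect_allele %in% .VALID_ALLELES), "invalid effect_allele")
  flag(!(df$other_allele %in% .VALID_ALLELES), "invalid other_allele")
  flag(!is.na(df$effect_allele) & !is.na(df$other_allele) &
         df$effect_allele == df$other_allele, "identical alleles")
  flag(!is.finite(df$beta), "non-finite beta")
  flag(!is.finite(df$se) | df$se <= 0, "non-positive se")
  flag(!is.finite(df$pvalue) | df$pvalue <= 0 | df$pvalue > 1, "pvalue outside (0,1]")
  flag(!is.finite(df$n) | df$n < 1 | df$n != round(df$n), "invalid n")
  eaf_bad <- !is.na(df$eaf) & (!is.finite(df$eaf) | df$eaf <= 0 | df$eaf >= 1)
  reason[eaf_bad & is.na(reason)] <- "eaf outside (0,1)"
  list(keep = is.na(reason), reason = reason)
}

#' Construct a validated trait table of summary statistics
#'
#' A trait table is a `data.frame` of per-SNP associations for one trait
#' (canonical columns `snp_id`, `chrom`, `pos`, `effect_allele`,
#' `other_allele`, `eaf`, `beta`, `se`, `pvalue`, `n`) carrying trait
#' metadata as attributes. For a binary trait, `beta` is the per-allele
#' log odds ratio, ln(OR). Rows violating the record invariants (alleles
#' must be single A/C/G/T bases and differ, `se > 0`, `pvalue` in (0,1],
#' `eaf` in (0,1) when present, positive integer `n` and `pos`) are
#' dropped and counted; duplicated `snp_id` among surviving rows is an
#' error. Effect-allele frequency may be missing: operations that need it
#' fail explicitly rather than impute.
#'
#' @param records `data.frame` with the canonical columns.
#' @param trait_id Identifier (GWAS accession, bacterial taxon name, ...).
#' @param trait_type `"quantitative"` or `"binary"`.
#' @param taxonomic_level Optional: one of phylum/class/order/family/genus
#'   for microbiota traits.
#' @return A `trait_table`: the validated rows with attributes `trait_id`,
#'   `trait_type`, `taxonomic_level`, `n_dropped` and `drop_reasons`.
#' @export
#' @examples
#' tt <- trait_table(data.frame(
#'   snp_id = "rs1", chrom = "1", pos = 1000L, effect_allele = "A",
#'   other_allele = "G", eaf = 0.3, beta = 0.1, se = 0.02,
#'   pvalue = 5e-7, n = 15000L), trait_id = "g.Example")
#' attr(tt, "n_dropped")
trait_table <- function(records, trait_id,
                        trait_type = c("quantitative", "binary"),
                        taxonomic_level = NULL) {
  trait_type <- match.arg(trait_type)
  if (!is.null(taxonomic_level)) {
    taxonomic_level <- match.arg(taxonomic_level,
                                 c("phylum", "class", "order", "family", "genus"))
  }
  missing_cols <- setdiff(.MANDATORY_FIELDS, names(records))
  if (length(missing_cols)) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!"eaf" %in% names(records)) records$eaf <- NA_real_
  df <- data.frame(
    snp_id = as.character(records$snp_id),
    chrom = as.character(records$chrom),
    pos = as.numeric(records$pos),
    effect_allele = toupper(as.character(records$effect_allele)),
    other_allele = toupper(as.character(records$other_allele)),
    eaf = as.numeric(records$eaf),
    beta = as.numeric(records$beta),
    se = as.numeric(records$se),
    pvalue = as.numeric(records$pvalue),
    n = as.numeric(records$n),
    stringsAsFactors = FALSE
  )
  v <- validate_rows(df)
  out <- df[v$keep, , drop = FALSE]
  if (nrow(out) == 0L) {
    stop("no valid summary-statistic rows for trait '", trait_id, "'",
         call. = FALSE)
  }
  dup <- out$snp_id[duplicated(out$snp_id)]
  if (length(dup)) {
    stop("duplicated snp_id in trait '", trait_id, "': ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  rownames(out) <- NULL
  structure(out,
            trait_id = trait_id,
            trait_type = trait_type,
            taxonomic_level = taxonomic_level,
            n_dropped = sum(!v$keep),
            drop_reasons = table(v$reason[!v$keep]),
            class = c("trait_table", "data.frame"))
}

# Preserve trait metadata when subsetting rows of a trait table.
retable <- function(df, template) {
  structure(df,
            trait_id = attr(template, "trait_id"),
            trait_type = attr(template, "trait_type"),
            taxonomic_level = attr(template, "taxonomic_level"),
            n_dropped = attr(template, "n_dropped"),
            drop_reasons = attr(template, "drop_reasons"),
            class = c("trait_table", "data.frame"))
}

#' Trait identifier of a trait table
#' @param x A `trait_table`.
#' @return Character scalar.
#' @export
trait_id <- function(x) attr(x, "trait_id")

#' @export
print.trait_table <- function(x, ...) {
  cat(sprintf("Trait table '%s' (%s%s): %d SNPs, %d rows dropped on read\n",
              attr(x, "trait_id"), attr(x, "trait_type"),
              if (!is.null(attr(x, "taxonomic_level"))) {
                paste0(", ", attr(x, "taxonomic_level"))
              } else "",
              nrow(x), attr(x, "n_dropped") %||% 0L))
  print(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat("...", nrow(x) - 10L, "more rows\n")
  invisible(x)
}

#' Read GWAS summary statistics from a delimited text file
#'
#' Reads a header-ed delimited table, renames columns through `column_map`,
#' and validates the rows (see [trait_table()]). Invalid rows are dropped
#' and counted; the count is reported via a message and stored in the
#' `n_dropped` attribute.
#'
#' @param path Path to a delimited text file with a header row.
#' @param column_map Named character vector mapping canonical field names
#'   (see [default_column_map()]) to the file's column names. The `eaf`
#'   mapping may be omitted; all other fields are mandatory.
#' @param trait_id,trait_type,taxonomic_level Trait metadata, as for
#'   [trait_table()].
#' @param sep Field delimiter (default tab).
#' @return A validated `trait_table`.
#' @export
read_sumstats <- function(path, column_map = default_column_map(),
                          trait_id, trait_type = c("quantitative", "binary"),
                          taxonomic_level = NULL, sep = "\t") {
  raw <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE,
                           check.names = FALSE)
  wanted <- intersect(.SUMSTAT_FIELDS, names(column_map))
  missing_map <- setdiff(.MANDATORY_FIELDS, wanted)
  if (length(missing_map)) {
    stop("column_map lacks mandatory field(s): ",
         paste(missing_map, collapse = ", "), call. = FALSE)
  }
  absent <- setdiff(unname(column_map[wanted]), names(raw))
  if (length(absent)) {
    stop("mapped column(s) not present in file: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  records <- stats::setNames(raw[, unname(column_map[wanted]), drop = FALSE],
                             wanted)
  tt <- trait_table(records, trait_id = trait_id, trait_type = trait_type,
                    taxonomic_level = taxonomic_level)
  if (attr(tt, "n_dropped") > 0L) {
    message(attr(tt, "n_dropped"), " row(s) dropped during validation for '",
            trait_id, "'")
  }
  tt
}

#' Write a trait table to tab-delimited text
#'
#' @param x A `trait_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(x, path) {
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], format_num, digits = 10L)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write MR result rows as a tab-delimited table
#'
#' Emits the report shape used throughout: one row per (trait, method)
#' with columns `id`, `method`, `p`, `or`, `ci_low`, `ci_high`, `n_snp`.
#' Numbers are written to 6 significant digits (scientific notation below
#' 1e-3) and round-trip through [read_results()] at that precision.
#'
#' @param results `data.frame` with columns `id`, `method`, `pvalue`, `or`,
#'   `ci_low`, `ci_high`, `n_snp` (the shape produced by [run_plan()] and
#'   [as.data.frame.mr_fit()]).
#' @param path Output path.
#' @return `path`, invisibly. Zero-row input writes a header-only file
#'   with a warning.
#' @export
write_results <- function(results, path) {
  cols <- c(id = "id", method = "method", p = "pvalue", or = "or",
            ci_low = "ci_low", ci_high = "ci_high", n_snp = "n_snp")
  missing_cols <- setdiff(unname(cols), names(results))
  if (length(missing_cols)) {
    stop("results lack column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  out <- results[, unname(cols), drop = FALSE]
  names(out) <- names(cols)
  if (nrow(out) == 0L) {
    warning("writing empty result table (header only)", call. = FALSE)
  }
  for (col in c("p", "or", "ci_low", "ci_high")) out[[col]] <- format_num(out[[col]])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a result table written by [write_results()]
#'
#' @param path Path to a results TSV.
#' @return `data.frame` with columns `id`, `method`, `pvalue`, `or`,
#'   `ci_low`, `ci_high`, `n_snp`.
#' @export
read_results <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  names(df)[names(df) == "p"] <- "pvalue"
  df
}

#' Export harmonized instruments for scatter-plot reconstruction
#'
#' Writes the per-SNP exposure/outcome effects and standard errors (the
#' data series behind MR scatter plots) as a TSV.
#'
#' @param instruments An `mr_instruments` table (see [harmonize()]).
#' @param path Output path.
#' @param kept_only Write only rows that survived harmonization/filters.
#' @return `path`, invisibly.
#' @export
write_instruments <- function(instruments, path, kept_only = TRUE) {
  df <- as.data.frame(instruments)
  if (kept_only) df <- df[df$keep, , drop = FALSE]
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], format_num, digits = 10L)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
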