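#' Canonical column dictionary
#'
#' Maps analyzer-style spellings of haematology columns onto the canonical
#' lower-snake-case names used throughout the package. Matching is performed
#' on names squashed to lowercase alphanumerics, so `"MN-LMALS-RET"`,
#' `"@MNLMALSRET"` and `"mn_lmals_ret"` are all recognised.
#'
#' @return Named character vector: names are squashed aliases, values are
#'   canonical column names.
#' @export
column_dictionary <- function() {
  c(
    subjectid = "subject_id", sampleid = "subject_id", id = "subject_id",
    hb = "hb", hgb = "hb", haemoglobin = "hb", hemoglobin = "hb",
    rbc = "rbc", hct = "hct", haematocrit = "hct", hematocrit = "hct",
    mcv = "mcv", mch = "mch", mchc = "mchc",
    rdw = "rdw", rdwcv = "rdw",
    mnlmalsret = "mn_lmals_ret", mnmalsret = "mn_mals_ret",
    mnlmalsnret = "mn_lmals_nret", mnvret = "mn_v_ret",
    mnvnret = "mn_v_nret", maf = "maf",
    label = "label", group = "label", diagnosis = "label"
  )
}

numeric_columns <- function() {
  c("hb", "rbc", "hct", "mcv", "mch", "mchc", "rdw",
    "mn_lmals_ret", "mn_mals_ret", "mn_lmals_nret",
    "mn_v_ret", "mn_v_nret", "maf")
}

#' Sanity bounds for physiologic fields
#'
#' Default plausibility bounds used to flag (never drop) out-of-range rows at
#' parse time. All numeric fields must additionally be strictly positive and
#' finite, except RDW which only needs to be non-negative.
#'
#' @param mcv,mch Length-2 numeric `(low, high)` bounds, fL and pg.
#' @return Named list of bounds.
#' @export
sanity_bounds <- function(mcv = c(40, 140), mch = c(10, 50)) {
  list(mcv = mcv, mch = mch)
}

new_cohort <- function(df, provenance = "", parse_report = NULL) {
  stopifnot(is.data.frame(df))
  if (!".flagged" %in% names(df)) df$.flagged <- FALSE
  if (!".flag_reason" %in% names(df)) df$.flag_reason <- ""
  structure(df,
            class = c("thal_cohort", "data.frame"),
            provenance = provenance,
            parse_report = parse_report)
}

#' Build a cohort from an in-memory data frame
#'
#' Renames columns through [column_dictionary()], coerces numeric fields,
#' validates labels against [group_labels()], and flags rows that violate
#' sanity bounds. Flagged rows are retained; exclusion is decided by each
#' downstream operation, not at parse time.
#'
#' @param df Data frame, one row per subject.
#' @param provenance Free-text source note stored on the cohort.
#' @param bounds Sanity bounds, see [sanity_bounds()].
#' @param autogen_ids If `TRUE` and no subject-identifier column is present,
#'   sequential ids `s1, s2, ...` are generated; otherwise this is an error.
#' @param column_map Optional named character vector of extra aliases
#'   (names = spellings in `df`, values = canonical names), applied before
#'   the built-in dictionary.
#' @return A `thal_cohort` (a data frame with canonical columns plus
#'   `.flagged`/`.flag_reason`, and attributes `provenance`, `parse_report`).
#' @export
as_cohort <- function(df, provenance = "", bounds = sanity_bounds(),
                      autogen_ids = FALSE, column_map = NULL) {
  stopifnot(is.data.frame(df))
  df <- as.data.frame(df, stringsAsFactors = FALSE)

  nm <- names(df)
  if (!is.null(column_map)) {
    hit <- match(squash_name(nm), squash_name(names(column_map)))
    nm[!is.na(hit)] <- unname(column_map[hit[!is.na(hit)]])
  }
  dict <- column_dictionary()
  hit <- match(squash_name(nm), names(dict))
  nm[!is.na(hit)] <- unname(dict[hit[!is.na(hit)]])
  names(df) <- nm

  if (!"subject_id" %in% names(df)) {
    if (!autogen_ids)
      stop("no subject identifier column found; set autogen_ids = TRUE to number rows",
           call. = FALSE)
    df$subject_id <- paste0("s", seq_len(nrow(df)))
  }
  df$subject_id <- as.character(df$subject_id)
  if (anyDuplicated(df$subject_id))
    stop("subject_id values must be unique within a cohort", call. = FALSE)

  n_missing <- integer(0)
  for (col in intersect(numeric_columns(), names(df))) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
    n_missing[[col]] <- sum(is.na(df[[col]]))
  }

  if ("label" %in% names(df)) {
    df$label <- as.character(df$label)
    bad <- !is.na(df$label) & df$label != "" & !(df$label %in% group_labels())
    if (any(bad))
      stop("unknown group label(s): ", paste(unique(df$label[bad]), collapse = ", "),
           call. = FALSE)
    df$label[!is.na(df$label) & df$label == ""] <- NA_character_
  }

  flagged <- rep(FALSE, nrow(df))
  reason <- rep("", nrow(df))
  add_flag <- function(idx, why) {
    idx <- which(idx)
    flagged[idx] <<- TRUE
    reason[idx] <<- ifelse(reason[idx] == "", why, paste(reason[idx], why, sep = "; "))
  }
  for (col in intersect(numeric_columns(), names(df))) {
    v <- df[[col]]
    ok_pos <- if (col == "rdw") v >= 0 else v > 0
    add_flag(!is.na(v) & (!is.finite(v) | !ok_pos),
             paste0(col, " non-positive or non-finite"))
  }
  for (col in intersect(names(bounds), names(df))) {
    v <- df[[col]]
    add_flag(!is.na(v) & (v < bounds[[col]][1] | v > bounds[[col]][2]),
             paste0(col, " outside [", bounds[[col]][1], ", ", bounds[[col]][2], "]"))
  }
  df$.flagged <- flagged
  df$.flag_reason <- reason

  report <- list(n_read = nrow(df), n_flagged = sum(flagged),
                 n_missing = as.list(n_missing))
  new_cohort(df, provenance = provenance, parse_report = report)
}

#' Read a cohort from delimited text
#'
#' Reads a comma- or tab-delimited file with a header row, one subject per
#' row, and maps columns onto the canonical dictionary. Rows violating sanity
#' bounds are retained but flagged. Parsing is locale-independent (decimal
#' point); missing values are empty cells or `NA`.
#'
#' @param path File path.
#' @param column_map Optional extra aliases, see [as_cohort()].
#' @param sep Field separator; `NULL` auto-detects comma vs tab from the
#'   header line.
#' @param autogen_ids Allow sequential ids when no identifier column exists.
#' @param bounds Sanity bounds, see [sanity_bounds()].
#' @return A `thal_cohort`; the parse report is in
#'   `attr(cohort, "parse_report")`.
#' @export
read_cohort <- function(path, column_map = NULL, sep = NULL,
                        autogen_ids = FALSE, bounds = sanity_bounds()) {
  if (!file.exists(path)) stop("cannot read cohort file: ", path, call. = FALSE)
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, na.strings = c("", "NA"),
                          check.names = FALSE, quote = "\"", comment.char = "")
  as_cohort(df, provenance = path, bounds = bounds,
            autogen_ids = autogen_ids, column_map = column_map)
}

#' Subset a cohort by group label
#'
#' @param cohort A `thal_cohort`.
#' @param groups Character vector of labels to keep.
#' @return The labelled subset, still a `thal_cohort`.
#' @export
cohort_subset <- function(cohort, groups) {
  stopifnot(inherits(cohort, "thal_cohort"), "label" %in% names(cohort))
  keep <- !is.na(cohort$label) & cohort$label %in% groups
  new_cohort(as.data.frame(cohort)[keep, , drop = FALSE],
             provenance = attr(cohort, "provenance"))
}

#' @export
print.thal_cohort <- function(x, ...) {
  rep <- attr(x, "parse_report")
  cat(sprintf("<thal_cohort> %d subjects", nrow(x)))
  if ("label" %in% names(x)) {
    tab <- table(x$label, useNA = "no")
    if (length(tab))
      cat(" (", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), ")", sep = "")
  }
  cat("\n")
  if (!is.null(rep)) cat(sprintf("  flagged rows: %d\n", rep$n_flagged))
  print(utils::head(as.data.frame(x), 6))
  invisible(x)
}

#' Write a result table with a JSON metadata sidecar
#'
#' Writes a delimited text file (comma for `.csv`, tab otherwise) with stable
#' column order and full double precision (15 significant digits), plus a
#' `<path>.meta.json` sidecar recording the package version, the seed and a
#' digest of the configuration used. The sidecar carries no timestamp, so
#' identical runs produce byte-identical outputs.
#'
#' @param table A data frame (scores, ROC points, accuracy summary, ...).
#' @param path Output file path.
#' @param seed Seed used by the producing run, if any.
#' @param config Configuration object to digest into the sidecar.
#' @param sidecar Write the metadata sidecar? Default `TRUE`.
#' @return Invisibly, the path written.
#' @export
write_results <- function(table, path, seed = NULL, config = NULL, sidecar = TRUE) {
  stopifnot(is.data.frame(table))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- as.data.frame(table)
  for (col in names(df))
    if (is.numeric(df[[col]])) df[[col]] <- format(df[[col]], digits = 15, trim = TRUE,
                                                   scientific = FALSE)
  ok <- tryCatch({
    utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE,
                       na = "NA")
    TRUE
  }, error = function(e) stop("cannot write results to ", path, ": ",
                              conditionMessage(e), call. = FALSE))
  if (sidecar) {
    meta <- list(
      package = "thalscreen",
      version = as.character(utils::packageVersion("thalscreen")),
      seed = seed,
      config_digest = config_digest(config),
      columns = names(table),
      n_rows = nrow(table)
    )
    jsonlite::write_json(meta, paste0(path, ".meta.json"),
                         auto_unbox = TRUE, null = "null", digits = NA)
  }
  invisible(path)
}

# md5 of the canonical JSON form of a config (NULL -> NA)
config_digest <- function(config) {
  if (is.null(config)) return(NA_character_)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA, force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}
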