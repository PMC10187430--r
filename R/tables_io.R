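#' Protein quantification table
#'
#' Container for a label-free quantification (LFQ) protein matrix with
#' per-sample metadata: one row per protein accession, one column per sample.
#' A value of 0 means "not detected"; blank cells in the on-disk TSV are read
#' as 0, matching the convention of protein-level search-engine exports.
#'
#' @param intensities numeric matrix, proteins x samples, finite and
#'   non-negative; rownames are accessions, colnames are sample ids.
#' @param samples data.frame with columns `sample_id`, `lineage` (one of
#'   `"FT"`, `"HGSOC"`), `source` (one of `"cell_line"`, `"tissue"`),
#'   `unit_id` (cell line or explant/patient id) and `replicate`
#'   (positive integer). Row order defines sample order.
#' @return An object of class `protein_quant_table` with elements
#'   `accessions`, `samples` and `intensities`.
#' @export
protein_quant_table <- function(intensities, samples) {
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  req <- c("sample_id", "lineage", "source", "unit_id", "replicate")
  missing_cols <- setdiff(req, names(samples))
  if (length(missing_cols) > 0L) {
    stop("sample metadata is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  samples$sample_id <- as.character(samples$sample_id)
  samples$unit_id <- as.character(samples$unit_id)
  samples$replicate <- as.integer(samples$replicate)
  accessions <- rownames(intensities)
  if (is.null(accessions)) stop("intensity matrix must have accession rownames")
  accessions <- trimws(accessions)
  rownames(intensities) <- accessions
  if (anyDuplicated(accessions)) {
    stop("duplicate accession(s): ",
         paste(unique(accessions[duplicated(accessions)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(samples$sample_id)) {
    stop("duplicate sample_id in metadata", call. = FALSE)
  }
  if (ncol(intensities) != nrow(samples)) {
    stop("intensity matrix has ", ncol(intensities),
         " columns but metadata describes ", nrow(samples), " samples",
         call. = FALSE)
  }
  bad_lin <- setdiff(unique(samples$lineage), c("FT", "HGSOC"))
  if (length(bad_lin) > 0L) {
    stop("unknown lineage value(s): ", paste(bad_lin, collapse = ", "),
         call. = FALSE)
  }
  bad_src <- setdiff(unique(samples$source), c("cell_line", "tissue"))
  if (length(bad_src) > 0L) {
    stop("unknown source value(s): ", paste(bad_src, collapse = ", "),
         call. = FALSE)
  }
  if (any(samples$replicate < 1L) || anyNA(samples$replicate)) {
    stop("replicate must be a positive integer", call. = FALSE)
  }
  if (!is.null(colnames(intensities)) &&
      !identical(colnames(intensities), samples$sample_id)) {
    extra <- setdiff(colnames(intensities), samples$sample_id)
    if (length(extra) > 0L) {
      stop("sample_id mismatch: matrix column(s) ",
           paste(extra, collapse = ", "), " absent from metadata",
           call. = FALSE)
    }
    missing_s <- setdiff(samples$sample_id, colnames(intensities))
    if (length(missing_s) > 0L) {
      stop("sample_id mismatch: metadata sample(s) ",
           paste(missing_s, collapse = ", "), " absent from matrix",
           call. = FALSE)
    }
    intensities <- intensities[, samples$sample_id, drop = FALSE]
  }
  colnames(intensities) <- samples$sample_id
  if (anyNA(intensities) || any(!is.finite(intensities))) {
    stop("intensities must be finite (use 0 or blank for not detected)",
         call. = FALSE)
  }
  if (any(intensities < 0)) stop("negative intensity value", call. = FALSE)
  structure(
    list(accessions = accessions, samples = samples, intensities = intensities),
    class = "protein_quant_table"
  )
}

#' @export
print.protein_quant_table <- function(x, ...) {
  cat("Protein quantification table: ", length(x$accessions), " proteins x ",
      nrow(x$samples), " samples\n", sep = "")
  tab <- table(x$samples$lineage, x$samples$source)
  print(tab)
  invisible(x)
}

#' Named set of protein accessions
#'
#' @param name non-empty label for the set.
#' @param members character vector of accessions; whitespace is stripped and
#'   duplicates removed.
#' @return An object of class `accession_set` with elements `name`, `members`
#'   (sorted unique accessions) and `n_input` (count before deduplication).
#' @export
accession_set <- function(name, members) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("accession set name must be a non-empty string", call. = FALSE)
  }
  members <- trimws(as.character(members))
  members <- members[nzchar(members)]
  n_input <- length(members)
  members <- sort(unique(members))
  structure(list(name = name, members = members, n_input = n_input),
            class = "accession_set")
}

#' @export
print.accession_set <- function(x, ...) {
  cat("Accession set '", x$name, "': ", length(x$members), " members\n",
      sep = "")
  invisible(x)
}

#' @export
length.accession_set <- function(x) length(x$members)

#' Per-subject marker score table
#'
#' Holds continuous marker readouts (e.g. per-channel chip fluorescence) for
#' case/control subjects, the substrate for ROC and panel analysis.
#'
#' @param subjects data.frame with columns `subject_id`, `label` (values
#'   `"case"`/`"control"`) and optionally `stage`.
#' @param values numeric matrix, subjects x markers, with marker colnames.
#' @param background optional per-subject numeric vector (negative-control
#'   channel readout).
#' @return An object of class `marker_score_table`.
#' @export
marker_score_table <- function(subjects, values, background = NULL) {
  subjects <- as.data.frame(subjects, stringsAsFactors = FALSE)
  if (!all(c("subject_id", "label") %in% names(subjects))) {
    stop("subjects needs subject_id and label columns", call. = FALSE)
  }
  subjects$subject_id <- as.character(subjects$subject_id)
  if (anyDuplicated(subjects$subject_id)) {
    stop("duplicate subject_id: ",
         paste(unique(subjects$subject_id[duplicated(subjects$subject_id)]),
               collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(subjects$label), c("case", "control"))
  if (length(bad) > 0L) {
    stop("label(s) outside {case, control}: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(colnames(values))) stop("values must have marker colnames")
  if (anyDuplicated(colnames(values))) stop("duplicate marker names")
  if (nrow(values) != nrow(subjects)) {
    stop("values rows (", nrow(values), ") != subjects (", nrow(subjects), ")",
         call. = FALSE)
  }
  rownames(values) <- subjects$subject_id
  if (!is.null(background)) {
    background <- as.numeric(background)
    if (length(background) != nrow(subjects)) {
      stop("background length must equal subject count", call. = FALSE)
    }
  }
  structure(
    list(subjects = subjects, markers = colnames(values), values = values,
         background = background),
    class = "marker_score_table"
  )
}

#' @export
print.marker_score_table <- function(x, ...) {
  cat("Marker score table: ", nrow(x$subjects), " subjects (",
      sum(x$subjects$label == "case"), " case / ",
      sum(x$subjects$label == "control"), " control), ",
      length(x$markers), " markers\n", sep = "")
  invisible(x)
}

#' Read a protein quantification matrix with sample metadata
#'
#' The matrix TSV has a header `accession` followed by one column per
#' sample id; blank or missing cells are read as 0 (not detected). The
#' metadata TSV carries columns `sample_id`, `lineage`, `source`, `unit_id`,
#' `replicate`. Sample order is taken from the metadata file.
#'
#' @param matrix_path path to the intensity TSV.
#' @param meta_path path to the sample-metadata TSV.
#' @return A [protein_quant_table()].
#' @export
read_quant_table <- function(matrix_path, meta_path) {
  mat <- utils::read.delim(matrix_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (names(mat)[1] != "accession") {
    stop("matrix TSV must start with an 'accession' column", call. = FALSE)
  }
  meta <- utils::read.delim(meta_path, check.names = FALSE,
                            stringsAsFactors = FALSE)
  acc <- trimws(as.character(mat$accession))
  if (anyDuplicated(acc)) {
    stop("duplicate accession(s) in ", matrix_path, ": ",
         paste(unique(acc[duplicated(acc)]), collapse = ", "), call. = FALSE)
  }
  m <- as.matrix(mat[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  m[is.na(m)] <- 0
  rownames(m) <- acc
  protein_quant_table(m, meta)
}

#' Write a protein quantification table to TSV files
#'
#' @param table a [protein_quant_table()].
#' @param matrix_path,meta_path output paths.
#' @return The input, invisibly.
#' @export
write_quant_table <- function(table, matrix_path, meta_path) {
  df <- data.frame(accession = table$accessions, table$intensities,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(table$samples, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(table)
}

#' Read a plain-text accession list
#'
#' One accession per line; lines starting with `#` are comments; surrounding
#' whitespace is stripped; duplicates are removed (the original line count is
#' kept in `n_input` as provenance).
#'
#' @param path file path.
#' @param name label for the resulting set (default: file base name).
#' @return An [accession_set()].
#' @export
read_accession_list <- function(path, name = NULL) {
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    stop("accession list ", path, " is empty after comment stripping",
         call. = FALSE)
  }
  accession_set(name, lines)
}

#' Write an accession set as a plain-text list
#' @param set an [accession_set()].
#' @param path output path.
#' @return The input, invisibly.
#' @export
write_accession_list <- function(set, path) {
  writeLines(c(paste0("# ", set$name), set$members), path)
  invisible(set)
}

#' Read a per-subject marker score CSV
#'
#' Expected columns: `subject_id`, `label`, optional `stage`, optional
#' `background`, then one column per marker. Labels are matched
#' case-insensitively against `"case"`/`"control"`; additional cohort-specific
#' vocabulary (e.g. `"HGSOC"` for cases, `"Healthy"` for controls) is supplied
#' through `label_map`, not hard-coded.
#'
#' @param path CSV path.
#' @param label_map named character vector mapping raw labels to `"case"` or
#'   `"control"`, e.g. `c(HGSOC = "case", Healthy = "control")`. Matching is
#'   case-insensitive.
#' @return A [marker_score_table()].
#' @export
read_score_table <- function(path, label_map = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("subject_id", "label") %in% names(df))) {
    stop("score CSV needs subject_id and label columns", call. = FALSE)
  }
  map <- c(case = "case", control = "control")
  if (!is.null(label_map)) {
    stopifnot(all(label_map %in% c("case", "control")))
    map <- c(map, structure(unname(label_map), names = tolower(names(label_map))))
  }
  raw_orig <- trimws(as.character(df$label))
  raw <- tolower(raw_orig)
  if (!all(raw %in% names(map))) {
    stop("unrecognized label(s): ",
         paste(unique(raw_orig[!raw %in% names(map)]), collapse = ", "),
         "; extend label_map", call. = FALSE)
  }
  subjects <- data.frame(subject_id = df$subject_id,
                         label = unname(map[raw]),
                         stringsAsFactors = FALSE)
  if ("stage" %in% names(df)) subjects$stage <- as.character(df$stage)
  background <- if ("background" %in% names(df)) as.numeric(df$background)
  marker_cols <- setdiff(names(df),
                         c("subject_id", "label", "stage", "background"))
  if (length(marker_cols) == 0L) stop("no marker columns found", call. = FALSE)
  values <- as.matrix(df[, marker_cols, drop = FALSE])
  marker_score_table(subjects, values, background)
}

#' Write a marker score table as CSV
#' @param table a [marker_score_table()].
#' @param path output path.
#' @return The input, invisibly.
#' @export
write_score_table <- function(table, path) {
  df <- table$subjects
  if (!is.null(table$background)) df$background <- table$background
  df <- cbind(df, as.data.frame(table$values, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(table)
}

#' Split marker scores into control and case vectors
#'
#' @param table a [marker_score_table()].
#' @param marker marker name.
#' @return list with numeric vectors `controls` and `cases`.
#' @export
marker_groups <- function(table, marker) {
  if (!marker %in% table$markers) {
    stop("marker '", marker, "' not in table", call. = FALSE)
  }
  v <- table$values[, marker]
  list(controls = unname(v[table$subjects$label == "control"]),
       cases = unname(v[table$subjects$label == "case"]))
}
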