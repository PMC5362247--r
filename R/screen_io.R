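# Tabular I/O for screen artifacts: plate layouts, raw measurements, siRNA
# library maps, score exports and expression tables.  All files are delimited
# text with a header row; tab-separated on output, comma accepted on input.

WELL_ROLES <- c("sample", "pos_control", "neg_control", "scrambled_control", "empty")

#' Canonicalize 384-well plate addresses
#'
#' Addresses are row letter `A`--`P` plus column `1`--`24`.  Leading zeros in
#' the column ("A01") are tolerated on input and stripped on output, so the
#' canonical form of "A01" is "A1".
#'
#' @param well character vector of well addresses.
#' @return character vector of canonical addresses.
#' @examples
#' canonical_well(c("A01", "p24"))
#' @export
canonical_well <- function(well) {
  well <- toupper(trimws(as.character(well)))
  m <- regmatches(well, regexec("^([A-P])0*([0-9]{1,2})$", well))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) {
    stop("malformed well address: ", paste(unique(well[bad]), collapse = ", "),
         call. = FALSE)
  }
  row <- vapply(m, `[`, "", 2L)
  col <- as.integer(vapply(m, `[`, "", 3L))
  if (any(col < 1L | col > 24L)) {
    stop("well column out of range 1-24: ",
         paste(unique(well[col < 1L | col > 24L]), collapse = ", "),
         call. = FALSE)
  }
  paste0(row, col)
}

read_delim_table <- function(path, required, sep = "\t", what = "table") {
  if (!file.exists(path)) stop(what, " file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                          comment.char = "", stringsAsFactors = FALSE,
                          na.strings = c("NA", ""), check.names = FALSE,
                          colClasses = "character")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop(what, " file ", path, " lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0L) stop(what, " file ", path, " has no data rows", call. = FALSE)
  df
}

as_numeric_column <- function(x, column, path) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad) > 0L) {
    stop("non-numeric value in column '", column, "' of ", path,
         " at data line ", bad[1L], ": '", x[bad[1L]], "'", call. = FALSE)
  }
  out
}

#' Read a plate layout table
#'
#' Schema: `plate_id`, `replicate_id`, `well`, `role`, `content_id`.  Roles
#' must be one of sample, pos_control, neg_control, scrambled_control, empty;
#' sample wells must carry a pool identifier.
#'
#' @param path delimited text file.
#' @param sep field separator (default tab).
#' @return a `screen_layout` data frame.
#' @export
read_layout <- function(path, sep = "\t") {
  df <- read_delim_table(path, c("plate_id", "replicate_id", "well", "role", "content_id"),
                         sep = sep, what = "layout")
  df$well <- canonical_well(df$well)
  bad_role <- setdiff(unique(df$role), WELL_ROLES)
  if (length(bad_role) > 0L) {
    stop("unknown well role(s) in ", path, ": ", paste(bad_role, collapse = ", "),
         call. = FALSE)
  }
  key <- paste(df$plate_id, df$replicate_id, df$well)
  if (anyDuplicated(key)) {
    d <- df[duplicated(key), , drop = FALSE][1L, ]
    stop("duplicate well address in layout: plate ", d$plate_id,
         " replicate ", d$replicate_id, " well ", d$well, call. = FALSE)
  }
  if (!any(df$role == "sample")) stop("layout has no sample wells", call. = FALSE)
  no_pool <- df$role == "sample" & (is.na(df$content_id) | df$content_id == "")
  if (any(no_pool)) {
    stop("sample well without pool identifier: well ",
         df$well[no_pool][1L], " on plate ", df$plate_id[no_pool][1L],
         call. = FALSE)
  }
  class(df) <- c("screen_layout", "data.frame")
  df
}

#' Read a raw measurement table
#'
#' Schema: `plate_id`, `replicate_id`, `well`, `signal` (relative light
#' units, finite and non-negative).
#'
#' @inheritParams read_layout
#' @return a `measurement_set` data frame.
#' @export
read_measurements <- function(path, sep = "\t") {
  df <- read_delim_table(path, c("plate_id", "replicate_id", "well", "signal"),
                         sep = sep, what = "measurement")
  df$well <- canonical_well(df$well)
  df$signal <- as_numeric_column(df$signal, "signal", path)
  if (anyNA(df$signal) || any(!is.finite(df$signal)) || any(df$signal < 0)) {
    stop("signals must be finite and >= 0 in ", path, call. = FALSE)
  }
  key <- paste(df$plate_id, df$replicate_id, df$well)
  if (anyDuplicated(key)) {
    d <- df[duplicated(key), , drop = FALSE][1L, ]
    stop("duplicate measurement record: plate ", d$plate_id,
         " replicate ", d$replicate_id, " well ", d$well, call. = FALSE)
  }
  class(df) <- c("measurement_set", "data.frame")
  df
}

#' Read an siRNA library map
#'
#' Schema: `pool_id`, `gene`, `sirna_id`, optional `isoform_note`.  A pool
#' typically holds four siRNAs; a gene may own several pools (for example
#' isoform-specific pools).
#'
#' @inheritParams read_layout
#' @return a `sirna_library` data frame.
#' @export
read_library <- function(path, sep = "\t") {
  df <- read_delim_table(path, c("pool_id", "gene", "sirna_id"), sep = sep,
                         what = "library")
  if (!"isoform_note" %in% names(df)) df$isoform_note <- NA_character_
  if (anyDuplicated(paste(df$pool_id, df$sirna_id))) {
    stop("duplicate (pool_id, sirna_id) pair in ", path, call. = FALSE)
  }
  gene_per_pool <- tapply(df$gene, df$pool_id, function(g) length(unique(g)))
  if (any(gene_per_pool > 1L)) {
    stop("pool mapped to more than one gene: ",
         names(gene_per_pool)[gene_per_pool > 1L][1L], call. = FALSE)
  }
  class(df) <- c("sirna_library", "data.frame")
  df
}

#' Read an expression table
#'
#' Schema: `gene`, `fpkm_minus_dox`, `fpkm_plus_dox`; FPKM values are means
#' over replicates, finite and non-negative.
#'
#' @inheritParams read_layout
#' @return an `expression_table` data frame.
#' @export
read_expression <- function(path, sep = "\t") {
  df <- read_delim_table(path, c("gene", "fpkm_minus_dox", "fpkm_plus_dox"),
                         sep = sep, what = "expression")
  for (cn in c("fpkm_minus_dox", "fpkm_plus_dox")) {
    df[[cn]] <- as_numeric_column(df[[cn]], cn, path)
  }
  ok <- is.finite(df$fpkm_minus_dox) & is.finite(df$fpkm_plus_dox) &
    df$fpkm_minus_dox >= 0 & df$fpkm_plus_dox >= 0
  if (!all(ok)) stop("FPKM values must be finite and >= 0 in ", path, call. = FALSE)
  if (anyDuplicated(df$gene)) {
    stop("duplicate gene in expression table: ",
         df$gene[duplicated(df$gene)][1L], call. = FALSE)
  }
  class(df) <- c("expression_table", "data.frame")
  df
}

#' Load and cross-validate a screen bundle
#'
#' Reads a layout, a measurement table and a library map and checks that the
#' three agree: every measurement well exists in its layout and every sample
#' well's pool exists in the library.
#'
#' @param layout_path,measurement_path,library_path delimited text files.
#' @param sep field separator (default tab; pass "," for CSV input).
#' @return a `screen_bundle` list with elements `layout`, `measurements`,
#'   `library`.
#' @export
load_screen_bundle <- function(layout_path, measurement_path, library_path,
                               sep = "\t") {
  layout <- read_layout(layout_path, sep = sep)
  meas <- read_measurements(measurement_path, sep = sep)
  lib <- read_library(library_path, sep = sep)

  lay_key <- paste(layout$plate_id, layout$replicate_id, layout$well)
  mea_key <- paste(meas$plate_id, meas$replicate_id, meas$well)
  dangling <- setdiff(mea_key, lay_key)
  if (length(dangling) > 0L) {
    stop("measurement references unknown well: ", dangling[1L], call. = FALSE)
  }
  sample_pools <- unique(layout$content_id[layout$role == "sample"])
  unknown <- setdiff(sample_pools, unique(lib$pool_id))
  if (length(unknown) > 0L) {
    stop("sample well pool absent from library: ",
         paste(utils::head(unknown, 3L), collapse = ", "), call. = FALSE)
  }
  structure(list(layout = layout, measurements = meas, library = lib),
            class = "screen_bundle")
}

#' Write a screen bundle to a directory
#'
#' Emits `layout.tsv`, `measurements.tsv` and `library.tsv` in canonical
#' tab-separated form, suitable for byte-stable round trips.
#'
#' @param bundle a `screen_bundle`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_screen_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "screen_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(bundle$layout, file.path(dir, "layout.tsv"))
  write_tsv(bundle$measurements, file.path(dir, "measurements.tsv"))
  write_tsv(bundle$library, file.path(dir, "library.tsv"))
  invisible(dir)
}

#' Write a canonical tab-separated table
#'
#' UTF-8, header row, no quoting, `NA` for missing; numbers are formatted
#' with [format()] at full precision so that write/read round trips are
#' stable.
#'
#' @param df data frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  out <- as.data.frame(df)
  for (cn in names(out)) {
    if (is.numeric(out[[cn]])) {
      out[[cn]] <- vapply(out[[cn]], function(v) {
        if (is.na(v)) NA_character_ else format(v, digits = 15, scientific = FALSE)
      }, "")
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Load score-table exports
#'
#' Ingests delimited exports of primary-screen scores, counter-screen scores
#' and an expression table.  Column names vary between exports, so a mapping
#' from the documented schema names (`pool_id`, `gene`, `zscore`) to the
#' actual headers can be supplied.  Rows with a missing Z are dropped and
#' counted.  Counter-screen rows whose pool id matches `control_pattern` are
#' treated as scrambled (non-silencing) controls and returned separately.
#'
#' @param primary_path,counter_path,expression_path delimited text files;
#'   `counter_path` and `expression_path` may be `NULL`.
#' @param columns named list mapping schema names to file headers, e.g.
#'   `list(zscore = "Z score")`.
#' @param control_pattern regular expression identifying scrambled-control
#'   rows in the counter table by pool id.
#' @param sep field separator.
#' @return list with `primary` (named pool -> mean Z vector), `primary_genes`
#'   (pool -> gene map), `counter` (named vector), `control_z` (numeric),
#'   `expression` (an `expression_table` or `NULL`) and `dropped` (named drop
#'   counts).
#' @export
load_score_tables <- function(primary_path, counter_path = NULL,
                              expression_path = NULL,
                              columns = list(),
                              control_pattern = "^(SCRAMBLED|NSC|CTRL)",
                              sep = "\t") {
  defaults <- list(pool_id = "pool_id", gene = "gene", zscore = "zscore")
  map <- utils::modifyList(defaults, columns)

  read_scores <- function(path, what) {
    df <- read_delim_table(path, unlist(map[c("pool_id", "zscore")]),
                           sep = sep, what = what)
    z <- as_numeric_column(df[[map$zscore]], map$zscore, path)
    keep <- !is.na(z)
    n_drop <- sum(!keep)
    if (n_drop > 0L) {
      message(what, ": dropped ", n_drop, " row(s) with missing Z")
    }
    df <- df[keep, , drop = FALSE]
    z <- z[keep]
    if (length(z) == 0L) stop(what, " table ", path, " has no parseable rows", call. = FALSE)
    gene <- if (map$gene %in% names(df)) df[[map$gene]] else rep(NA_character_, nrow(df))
    list(z = stats::setNames(z, df[[map$pool_id]]), gene = gene, dropped = n_drop)
  }

  prim <- read_scores(primary_path, "primary scores")
  dropped <- c(primary = prim$dropped)

  counter_z <- NULL
  control_z <- numeric(0)
  if (!is.null(counter_path)) {
    ctr <- read_scores(counter_path, "counter scores")
    dropped["counter"] <- ctr$dropped
    is_ctrl <- grepl(control_pattern, names(ctr$z), ignore.case = TRUE)
    control_z <- unname(ctr$z[is_ctrl])
    counter_z <- ctr$z[!is_ctrl]
  }
  expr <- if (!is.null(expression_path)) read_expression(expression_path, sep = sep) else NULL

  list(primary = prim$z,
       primary_genes = stats::setNames(prim$gene, names(prim$z)),
       counter = counter_z,
       control_z = control_z,
       expression = expr,
       dropped = dropped)
}
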