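#' Sample tables of PEF electroporation / electrofusion measurements
#'
#' A sample table holds one row per pulsed-electric-field (PEF) condition:
#' the pulse width and field strength applied, the fraction of cells stained
#' by the small YO-PRO-1 dye (`yp_rate`, a proxy for small-pore formation),
#' the fraction stained by the larger propidium iodide dye (`pi_rate`, a
#' proxy for large-pore formation), the measured cell fusion rate, and an
#' optional train/test role used by the PLS workflow.
#'
#' @name sample_table
#' @details Required columns:
#' `sample_id`, `pulse_width_ns`, `field_strength_kv_cm`, `yp_rate`,
#' `pi_rate`, `fusion_rate`, `role`. Sample ids must be unique; `yp_rate`
#' and `pi_rate` must lie in \[0, 100\]; `role` is one of `"train"`,
#' `"test"`, `"unassigned"`.
NULL

.sample_table_columns <- c(
  "sample_id", "pulse_width_ns", "field_strength_kv_cm",
  "yp_rate", "pi_rate", "fusion_rate", "role"
)
.sample_roles <- c("train", "test", "unassigned")

#' Validate a PEF sample table
#'
#' Checks column presence and types, unique sample ids, dye-uptake rates in
#' \[0, 100\], non-negative fusion rates, legal roles, and absence of missing
#' values in numeric columns.
#'
#' @param table A data frame (see [sample_table]).
#' @param min_rows Minimum number of rows required (default 1).
#' @return The validated table, invisibly, with `role` normalised to
#'   character.
#' @export
validate_sample_table <- function(table, min_rows = 1L) {
  if (!is.data.frame(table)) {
    stop("sample table must be a data frame", call. = FALSE)
  }
  missing_cols <- setdiff(.sample_table_columns, names(table))
  if (length(missing_cols)) {
    stop("sample table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(table) < min_rows) {
    stop(sprintf("sample table needs at least %d row(s), got %d",
                 min_rows, nrow(table)), call. = FALSE)
  }
  table$sample_id <- as.character(table$sample_id)
  table$role <- as.character(table$role)
  if (anyDuplicated(table$sample_id)) {
    stop("sample_id values must be unique; duplicated: ",
         paste(unique(table$sample_id[duplicated(table$sample_id)]),
               collapse = ", "), call. = FALSE)
  }
  num_cols <- c("pulse_width_ns", "field_strength_kv_cm",
                "yp_rate", "pi_rate", "fusion_rate")
  for (cc in num_cols) {
    v <- table[[cc]]
    if (!is.numeric(v)) {
      stop(sprintf("column '%s' must be numeric", cc), call. = FALSE)
    }
    if (anyNA(v)) {
      stop(sprintf("column '%s' contains missing values (row %d)",
                   cc, which(is.na(v))[1L]), call. = FALSE)
    }
  }
  for (cc in c("yp_rate", "pi_rate")) {
    bad <- which(table[[cc]] < 0 | table[[cc]] > 100)
    if (length(bad)) {
      stop(sprintf("column '%s' must lie in [0, 100] (row %d)", cc, bad[1L]),
           call. = FALSE)
    }
  }
  if (any(table$fusion_rate < 0)) {
    stop("fusion_rate must be >= 0", call. = FALSE)
  }
  bad_role <- setdiff(unique(table$role), .sample_roles)
  if (length(bad_role)) {
    stop("unknown role value(s): ", paste(bad_role, collapse = ", "),
         call. = FALSE)
  }
  invisible(table)
}

#' Read a PEF sample table from CSV
#'
#' @param path Path to a CSV file with the columns documented in
#'   [sample_table].
#' @return A validated data frame.
#' @export
read_sample_table <- function(path) {
  if (!file.exists(path)) {
    stop("sample table file not found: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) {
    stop("no samples: ", path, call. = FALSE)
  }
  validate_sample_table(df)
  df$sample_id <- as.character(df$sample_id)
  df$role <- as.character(df$role)
  df
}

#' Write a PEF sample table to CSV
#'
#' @param table A validated sample table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sample_table <- function(table, path) {
  validate_sample_table(table)
  utils::write.csv(table[, .sample_table_columns], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' The packaged 12-sample electroporation / fusion table
#'
#' Returns the packaged table of 12 PEF conditions (8 training, 4 test) with
#' YO-PRO-1 and propidium-iodide electroporation rates and measured cell
#' fusion rates, including the published train/test role assignment. This
#' table is the canonical input of the PLS workflow.
#'
#' @return A 12-row sample table data frame.
#' @export
#' @examples
#' tab <- pef_sample_table()
#' subset(tab, role == "train")
pef_sample_table <- function() {
  path <- system.file("extdata", "pef_electroporation_samples.csv",
                      package = "pefpore", mustWork = TRUE)
  read_sample_table(path)
}
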