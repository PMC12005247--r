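# Cohort table input/output and validation.
#
# A cohort table has one row per genotype x environment x pot with the counts
# observed at each life stage: seeds planted, seedlings retained after
# germination (and, at low density, thinning), adults surviving, and seeds
# produced by those adults.

cohort_columns <- c("genotype", "environment", "pot", "seeds_planted",
                    "seedlings_retained", "adults", "seeds_produced")

#' Validate a cohort table
#'
#' Checks the structural invariants of a cohort table: required columns,
#' non-negative counts, and the stage ordering
#' `adults <= seedlings_retained <= seeds_planted` in every row. With
#' `density_map` supplied and `strict = TRUE`, additionally checks the
#' planting design: 30 seeds per pot in high-density environments and at most
#' one retained seedling per pot in low-density ones.
#'
#' @param df A data frame with the columns listed above.
#' @param density_map Optional named character vector mapping environment ids
#'   to `"high"`/`"low"`.
#' @param strict Also enforce the planting design (default `FALSE`).
#' @return The table as a tibble, classed `cohort_table`, invisibly usable as
#'   a plain data frame. Errors list the offending row numbers.
#' @export
validate_cohort <- function(df, density_map = NULL, strict = FALSE) {
  missing_cols <- setdiff(cohort_columns, names(df))
  if (length(missing_cols) > 0) {
    stop_domain("cohort table lacks columns: ",
                paste(missing_cols, collapse = ", "))
  }
  df <- tibble::as_tibble(df)[, cohort_columns]
  counts <- c("seeds_planted", "seedlings_retained", "adults",
              "seeds_produced")
  problems <- character()
  for (col in counts) {
    bad <- which(!is.finite(df[[col]]) | df[[col]] < 0)
    if (length(bad) > 0) {
      problems <- c(problems, paste0("negative or missing ", col, " in row(s) ",
                                     paste(utils::head(bad, 10), collapse = ", ")))
    }
  }
  bad <- which(df$adults > df$seedlings_retained)
  if (length(bad) > 0) {
    problems <- c(problems, paste0("adults > seedlings_retained in row(s) ",
                                   paste(utils::head(bad, 10), collapse = ", ")))
  }
  bad <- which(df$seedlings_retained > df$seeds_planted)
  if (length(bad) > 0) {
    problems <- c(problems, paste0("seedlings_retained > seeds_planted in row(s) ",
                                   paste(utils::head(bad, 10), collapse = ", ")))
  }
  if (strict && !is.null(density_map)) {
    dens <- density_map[df$environment]
    bad <- which(dens == "high" & df$seeds_planted != 30)
    if (length(bad) > 0) {
      problems <- c(problems, paste0("high-density pot without 30 seeds in row(s) ",
                                     paste(utils::head(bad, 10), collapse = ", ")))
    }
    bad <- which(dens == "low" & df$seedlings_retained > 1)
    if (length(bad) > 0) {
      problems <- c(problems, paste0("low-density pot with > 1 retained seedling in row(s) ",
                                     paste(utils::head(bad, 10), collapse = ", ")))
    }
  }
  if (length(problems) > 0) {
    stop_domain("invalid cohort table:\n  ", paste(problems, collapse = "\n  "))
  }
  class(df) <- c("cohort_table", class(df))
  df
}

#' Read a cohort table from CSV
#'
#' Reads a comma-separated cohort table with a header. `column_map` renames
#' nonstandard headers onto the canonical ones, so externally deposited
#' layouts can be loaded without editing the file: e.g.
#' `c(genotype = "accession_id", adults = "n_adult")` declares that the file
#' column `accession_id` holds the genotype id.
#'
#' @param path Path to a CSV file.
#' @param column_map Optional named character vector: names are canonical
#'   column names, values are the file's column names.
#' @param ... Passed to [validate_cohort()] (`density_map`, `strict`).
#' @return A validated `cohort_table` tibble.
#' @export
read_cohort_csv <- function(path, column_map = NULL, ...) {
  if (!file.exists(path)) stop_domain("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(column_map)) {
    missing_src <- setdiff(unname(column_map), names(df))
    if (length(missing_src) > 0) {
      stop_domain("column_map refers to absent column(s): ",
                  paste(missing_src, collapse = ", "))
    }
    for (canonical in names(column_map)) {
      df[[canonical]] <- df[[column_map[[canonical]]]]
      if (column_map[[canonical]] != canonical) {
        df[[column_map[[canonical]]]] <- NULL
      }
    }
  }
  df$genotype <- as.character(df$genotype)
  df$environment <- as.character(df$environment)
  validate_cohort(df, ...)
}

#' Write a cohort table to CSV
#'
#' @param table A cohort table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table)[, cohort_columns], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Infer pot density from environment labels
#'
#' Environment ids produced by [generate_cohort()] encode density as a
#' `_highdens` / `_lowdens` suffix; this helper recovers it. Supply an
#' explicit `density_map` to the pipeline for any other labelling scheme.
#'
#' @param environment Character vector of environment ids.
#' @return Character vector of `"high"` / `"low"` (NA when not encoded).
#' @export
infer_density <- function(environment) {
  out <- rep(NA_character_, length(environment))
  out[grepl("highdens", environment)] <- "high"
  out[grepl("lowdens", environment)] <- "low"
  out
}
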