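#' Read a cohort from CSV files
#'
#' Items and outcomes are joined on the `participant_id` key (first column of
#' each file); rows are canonicalised by sorting on the identifier, so a
#' write/read round trip reproduces the cohort. Validation is itemised:
#' duplicate or mismatched identifiers, missing cells, and out-of-range item
#' responses are reported with the offending rows/columns.
#'
#' @param items_csv Path to the item responses CSV (`participant_id` plus one
#'   integer column per item, values 1-5).
#' @param outcomes_csv Path to the outcomes CSV (`participant_id` plus one
#'   numeric column per outcome).
#' @param retest_csv Optional path to a second-administration items CSV whose
#'   identifiers are a subset of the first.
#' @return A validated `cohort`.
#' @export
read_cohort <- function(items_csv, outcomes_csv, retest_csv = NULL) {
  # all cells are read as text and converted with strtod so that doubles
  # written in shortest-roundtrip form restore bit-exactly
  read_raw <- function(path) {
    df <- readr::read_csv(path, col_types = readr::cols(
      .default = readr::col_character()), progress = FALSE)
    df[-1] <- lapply(df[-1], as.numeric)
    df
  }
  items <- read_raw(items_csv)
  outcomes <- read_raw(outcomes_csv)
  for (nm in c("items", "outcomes")) {
    df <- get(nm)
    if (names(df)[1] != "participant_id") {
      stop_rrscore(sprintf("First column of the %s file must be `participant_id`.", nm),
                   "rrscore_validation_error")
    }
    dup <- df$participant_id[duplicated(df$participant_id)]
    if (length(dup)) {
      stop_rrscore(sprintf("Duplicate participant ids in %s file: %s.",
                           nm, format_ids(unique(dup))),
                   "rrscore_validation_error")
    }
    if (anyNA(df)) {
      bad <- which(rowSums(is.na(df)) > 0)
      stop_rrscore(sprintf("Missing cells in %s file (rows %s); complete responses required.",
                           nm, format_ids(bad)), "rrscore_validation_error")
    }
  }
  only_items <- setdiff(items$participant_id, outcomes$participant_id)
  only_out <- setdiff(outcomes$participant_id, items$participant_id)
  if (length(only_items) || length(only_out)) {
    stop_rrscore(paste0(
      "Item and outcome files cover different participants.",
      if (length(only_items)) sprintf(" Missing outcomes for: %s.", format_ids(only_items)),
      if (length(only_out)) sprintf(" Missing items for: %s.", format_ids(only_out))),
      "rrscore_validation_error")
  }
  items <- items[order(items$participant_id), ]
  outcomes <- outcomes[order(outcomes$participant_id), ]
  X <- as.matrix(items[-1])
  bad <- which(X < 1 | X > 5 | X != round(X), arr.ind = TRUE)
  if (nrow(bad)) {
    stop_rrscore(sprintf(
      "Item responses outside 1..5 (or non-integer), e.g. participant %s, item %s (value %s).",
      items$participant_id[bad[1, 1]], colnames(X)[bad[1, 2]],
      format(X[bad[1, , drop = FALSE]])), "rrscore_validation_error")
  }
  storage.mode(X) <- "integer"
  rownames(X) <- items$participant_id
  Y <- as.matrix(outcomes[-1])
  rownames(Y) <- outcomes$participant_id
  cohort <- new_cohort(items$participant_id, X, Y)
  if (!is.null(retest_csv)) {
    retest <- read_raw(retest_csv)
    unknown <- setdiff(retest$participant_id, items$participant_id)
    if (length(unknown)) {
      stop_rrscore(sprintf("Retest ids absent from the items file: %s.",
                           format_ids(unknown)), "rrscore_validation_error")
    }
    retest <- retest[order(retest$participant_id), ]
    X2 <- as.matrix(retest[-1])
    if (anyNA(X2) || any(X2 < 1 | X2 > 5 | X2 != round(X2))) {
      stop_rrscore("Retest responses must be complete integers in 1..5.",
                   "rrscore_validation_error")
    }
    storage.mode(X2) <- "integer"
    rownames(X2) <- retest$participant_id
    colnames(X2) <- colnames(X)
    cohort$X_retest <- X2
  }
  validate_cohort(cohort)
}

#' Write a cohort to CSV files
#'
#' Writes `items.csv`, `outcomes.csv` and (when present) `retest.csv` into
#' `dir`. Doubles are written in shortest round-trip representation, so
#' `read_cohort()` restores the matrices exactly.
#'
#' @param cohort A `cohort`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(items = file.path(dir, "items.csv"),
             outcomes = file.path(dir, "outcomes.csv"))
  readr::write_csv(dplyr::bind_cols(
    tibble::tibble(participant_id = cohort$participant_ids),
    tibble::as_tibble(cohort$X)), paths["items"])
  readr::write_csv(dplyr::bind_cols(
    tibble::tibble(participant_id = cohort$participant_ids),
    tibble::as_tibble(cohort$Y)), paths["outcomes"])
  if (!is.null(cohort$X_retest)) {
    paths["retest"] <- file.path(dir, "retest.csv")
    readr::write_csv(dplyr::bind_cols(
      tibble::tibble(participant_id = rownames(cohort$X_retest)),
      tibble::as_tibble(cohort$X_retest)), paths["retest"])
  }
  invisible(paths)
}
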