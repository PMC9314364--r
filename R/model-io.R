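#' Save / load a reduced-rank model
#'
#' A model is written as a directory holding `model.json` (rank, singular
#' values, standardiser vectors, dimension names) and two CSV matrices
#' `B.csv` and `A.csv`. Doubles are written in shortest round-trip form, so
#' `read_rrr_model(write_rrr_model(m, d))` reproduces the model to full
#' float precision.
#'
#' @param model An `rrr_model`.
#' @param dir Directory to write to (created if absent).
#' @return `write_rrr_model()` returns `dir` invisibly; `read_rrr_model()`
#'   returns the restored `rrr_model`.
#' @export
write_rrr_model <- function(model, dir) {
  stopifnot(inherits(model, "rrr_model"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  # doubles are serialised as %.17g strings: JSON writers round to 15
  # significant digits, which is not enough for a bit-exact round trip
  full <- function(x) sprintf("%.17g", x)
  header <- list(
    class = "rrr_model",
    rank = model$rank,
    n_train = model$n_train,
    training_loss = full(model$training_loss),
    singular_values = full(model$singular_values),
    x_means = full(model$x_standardizer$means),
    x_sds = full(model$x_standardizer$sds),
    y_means = full(model$y_standardizer$means),
    y_sds = full(model$y_standardizer$sds),
    item_names = rownames(model$B),
    outcome_names = rownames(model$A),
    dim_names = colnames(model$B)
  )
  jsonlite::write_json(header, file.path(dir, "model.json"),
                       auto_unbox = TRUE, digits = NA)
  write_matrix_csv(model$B, file.path(dir, "B.csv"))
  write_matrix_csv(model$A, file.path(dir, "A.csv"))
  invisible(dir)
}

#' @rdname write_rrr_model
#' @export
read_rrr_model <- function(dir) {
  header <- jsonlite::read_json(file.path(dir, "model.json"), simplifyVector = TRUE)
  B <- read_matrix_csv(file.path(dir, "B.csv"))
  A <- read_matrix_csv(file.path(dir, "A.csv"))
  dimnames(B) <- list(header$item_names, header$dim_names)
  dimnames(A) <- list(header$outcome_names, header$dim_names)
  num <- function(x) as.numeric(x)
  x_std <- structure(list(means = stats::setNames(num(header$x_means), header$item_names),
                          sds = stats::setNames(num(header$x_sds), header$item_names)),
                     class = "standardizer")
  y_std <- structure(list(means = stats::setNames(num(header$y_means), header$outcome_names),
                          sds = stats::setNames(num(header$y_sds), header$outcome_names)),
                     class = "standardizer")
  structure(list(B = B, A = A, rank = as.integer(header$rank),
                 singular_values = num(header$singular_values),
                 x_standardizer = x_std, y_standardizer = y_std,
                 training_loss = num(header$training_loss),
                 n_train = header$n_train),
            class = "rrr_model")
}

write_matrix_csv <- function(M, path) {
  readr::write_csv(tibble::as_tibble(M, .name_repair = "minimal"), path)
  invisible(path)
}

# read all cells as text and convert with strtod (correctly rounded), so the
# shortest-roundtrip doubles written by write_matrix_csv restore bit-exactly
read_matrix_csv <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  matrix(as.numeric(unlist(df)), nrow = nrow(df),
         dimnames = list(NULL, names(df)))
}
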