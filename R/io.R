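#' Write a simulated dataset to delimited text files
#'
#' Writes `responses.csv` (persons x items, 0/1, header = item ids),
#' `times.csv` (persons x items, seconds, full precision), `pattern.tsv`
#' (`item_id`, `group_id`) and `truth.json` (all generating parameters plus
#' the configuration). Persons are rows and items are columns throughout;
#' times are stored in seconds (the log transform is internal only);
#' missing cells are empty.
#'
#' @param sim a `bfhm_sim` from [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "bfhm_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(responses = file.path(dir, "responses.csv"),
             times = file.path(dir, "times.csv"),
             pattern = file.path(dir, "pattern.tsv"),
             truth = file.path(dir, "truth.json"))
  write_matrix_csv(sim$U, paths["responses"])
  write_matrix_csv(sim$T, paths["times"])
  write.table(data.frame(item_id = sim$pattern$item_ids,
                         group_id = sim$pattern$group_of),
              paths["pattern"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  tr <- sim$truth
  truth_json <- list(
    items = tr$items[c("a_g", "a_s", "d", "alpha_g", "alpha_s", "beta",
                       "sigma")],
    persons = list(theta_g = tr$persons$theta_g,
                   theta_s = tr$persons$theta_s,
                   tau_g = tr$persons$tau_g, tau_s = tr$persons$tau_s),
    structure = tr$structure,
    config = tr$config[setdiff(names(tr$config), "d_beta_cov")],
    d_beta_cov = as.vector(tr$config$d_beta_cov),
    variant = tr$spec$variant, seed = tr$seed)
  jsonlite::write_json(truth_json, paths["truth"], digits = NA,
                       auto_unbox = TRUE, null = "null")
  invisible(paths)
}

write_matrix_csv <- function(x, path) {
  df <- as.data.frame(x)
  # full-precision, locale-independent serialization
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(colnames(x), collapse = ","), con)
  body <- apply(df, 1, function(row) {
    paste(ifelse(is.na(row), "",
                 vapply(as.numeric(row), format, character(1),
                        digits = 17, scientific = FALSE, trim = TRUE)),
          collapse = ",")
  })
  writeLines(body, con)
}

read_matrix_csv <- function(path, what) {
  if (!file.exists(path)) stop(sprintf("%s file not found: %s", what, path))
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = "character", na.strings = "")
  m <- matrix(NA_real_, nrow(df), ncol(df),
              dimnames = list(NULL, colnames(df)))
  for (j in seq_len(ncol(df))) {
    v <- df[[j]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(num))
    if (length(bad))
      stop(sprintf("non-numeric value '%s' in %s at row %d, column '%s'",
                   v[bad[1]], what, bad[1], colnames(df)[j]))
    m[, j] <- num
  }
  m
}

#' Read a joint RA/RT dataset from delimited text files
#'
#' Reads and cross-validates the three on-disk pieces: a 0/1 response
#' matrix, a positive response-time matrix (both CSV, persons as rows,
#' header row of item ids, empty cells = missing) and a tab-separated
#' loading pattern mapping every item id to exactly one group id. Items are
#' ordered as in the response header. Validation failures name the
#' offending cell or item.
#'
#' @param responses_path,times_path,pattern_path file paths.
#' @return list of class `dataset_bundle` with `U`, `T`, `pattern`,
#'   `item_ids`, `n_missing` and provenance (`sources`, md5 `checksums`).
#' @export
read_dataset <- function(responses_path, times_path, pattern_path) {
  U <- read_matrix_csv(responses_path, "responses")
  T_mat <- read_matrix_csv(times_path, "times")
  if (!file.exists(pattern_path))
    stop("pattern file not found: ", pattern_path)
  pat <- utils::read.delim(pattern_path, colClasses = "character")
  if (!all(c("item_id", "group_id") %in% names(pat)))
    stop("pattern file must have columns item_id and group_id")
  item_ids <- colnames(U)
  if (anyDuplicated(item_ids))
    stop("duplicate item id in responses header: ",
         item_ids[duplicated(item_ids)][1])
  if (!all(dim(U) == dim(T_mat)))
    stop("responses and times disagree on dimensions")
  if (!identical(colnames(T_mat), item_ids))
    stop("responses and times disagree on item ids")
  if (anyDuplicated(pat$item_id))
    stop("item assigned to more than one group in pattern: ",
         pat$item_id[duplicated(pat$item_id)][1])
  missing_items <- setdiff(item_ids, pat$item_id)
  if (length(missing_items))
    stop("item missing from pattern: ", missing_items[1])
  bad_u <- which(!is.na(U) & !(U %in% c(0, 1)), arr.ind = TRUE)
  if (nrow(bad_u))
    stop(sprintf("response outside {0,1} at row %d, column '%s'",
                 bad_u[1, 1], item_ids[bad_u[1, 2]]))
  bad_t <- which(!is.na(T_mat) & T_mat <= 0, arr.ind = TRUE)
  if (nrow(bad_t))
    stop(sprintf("non-positive time at row %d, column '%s'",
                 bad_t[1, 1], item_ids[bad_t[1, 2]]))
  grp_raw <- pat$group_id[match(item_ids, pat$item_id)]
  grp <- as.integer(factor(grp_raw, levels = unique(grp_raw)))
  pattern <- loading_pattern(grp, item_ids = item_ids)
  structure(
    list(U = U, T = T_mat, pattern = pattern, item_ids = item_ids,
         n_missing = sum(is.na(U)) + sum(is.na(T_mat)),
         sources = c(responses = responses_path, times = times_path,
                     pattern = pattern_path),
         checksums = tools::md5sum(c(responses_path, times_path,
                                     pattern_path))),
    class = "dataset_bundle")
}
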