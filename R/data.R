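# Reading, validation and design encoding of per-participant trial tables.

trial_schema_cols <- function() {
  c("id", "center", "arm", "sex", "education", "age",
    "audit_total_baseline", "audit_c_baseline",
    "audit_total_fu", "audit_c_fu", "completed")
}

#' Read a per-participant trial table from CSV
#'
#' Reads the canonical schema written by [write_trial_csv()] and validates
#' every row: AUDIT total scores in \[0, 40\], AUDIT-C in \[0, 12\],
#' AUDIT-C never exceeding the matching total, follow-up fields present
#' exactly when `completed = 1`, and categorical levels as documented
#' (`arm` control/bi, `sex` male/female, `education`
#' incomplete/complete/superior).
#'
#' @param path CSV file path.
#' @param mapping Optional named character vector (or path to a `key=value`
#'   text file) recoding non-canonical category spellings to the canonical
#'   ones before validation, e.g. `c(Control = "control")`.
#' @return A validated trial table (`data.frame`, class `trial_table`),
#'   row order preserved.
#' @export
read_trial_csv <- function(path, mapping = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  missing_cols <- setdiff(trial_schema_cols(), names(raw))
  if (length(missing_cols))
    stop("trial CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  raw <- raw[, trial_schema_cols(), drop = FALSE]

  if (!is.null(mapping)) {
    if (length(mapping) == 1 && is.null(names(mapping)) && file.exists(mapping)) {
      kv <- strsplit(trimws(readLines(mapping, warn = FALSE)), "=", fixed = TRUE)
      kv <- kv[vapply(kv, length, 1L) == 2]
      mapping <- stats::setNames(vapply(kv, `[`, "", 2),
                                 vapply(kv, `[`, "", 1))
    }
    for (col in c("arm", "sex", "education")) {
      hit <- raw[[col]] %in% names(mapping)
      raw[[col]][hit] <- unname(mapping[raw[[col]][hit]])
    }
  }

  num <- function(col) suppressWarnings(as.numeric(ifelse(raw[[col]] == "",
                                                          NA, raw[[col]])))
  tab <- data.frame(
    id = raw$id,
    center = raw$center,
    arm = raw$arm,
    sex = raw$sex,
    education = raw$education,
    age = num("age"),
    audit_total_baseline = as.integer(num("audit_total_baseline")),
    audit_c_baseline = as.integer(num("audit_c_baseline")),
    audit_total_fu = as.integer(num("audit_total_fu")),
    audit_c_fu = as.integer(num("audit_c_fu")),
    completed = as.integer(num("completed")),
    stringsAsFactors = FALSE
  )
  validate_trial_table(tab)
}

#' Validate a trial table
#'
#' Checks the invariants of the per-participant schema and returns the
#' table classed as `trial_table`. Errors name the offending column and the
#' participant id of the first bad row.
#'
#' @param tab A data frame with the canonical trial columns.
#' @return The validated table.
#' @export
validate_trial_table <- function(tab) {
  missing_cols <- setdiff(trial_schema_cols(), names(tab))
  if (length(missing_cols))
    stop("trial table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)

  bad <- function(cond, col, msg) {
    i <- which(cond)
    if (length(i))
      stop(sprintf("invalid %s for participant id %s: %s",
                   col, tab$id[i[1]], msg), call. = FALSE)
  }
  in_range <- function(x, lo, hi) !is.na(x) & (x < lo | x > hi)

  bad(!tab$arm %in% c("control", "bi"), "arm", "must be control or bi")
  bad(!tab$sex %in% c("male", "female"), "sex", "must be male or female")
  bad(!tab$education %in% c("incomplete", "complete", "superior"),
      "education", "must be incomplete, complete or superior")
  bad(is.na(tab$age) | tab$age <= 0, "age", "must be a positive number")
  bad(is.na(tab$audit_total_baseline) |
        in_range(tab$audit_total_baseline, 0, 40),
      "audit_total_baseline", "must be an integer in [0, 40]")
  bad(is.na(tab$audit_c_baseline) | in_range(tab$audit_c_baseline, 0, 12),
      "audit_c_baseline", "must be an integer in [0, 12]")
  bad(in_range(tab$audit_total_fu, 0, 40), "audit_total_fu",
      "must be an integer in [0, 40] or missing")
  bad(in_range(tab$audit_c_fu, 0, 12), "audit_c_fu",
      "must be an integer in [0, 12] or missing")
  bad(tab$audit_c_baseline > tab$audit_total_baseline, "audit_c_baseline",
      "AUDIT-C cannot exceed the AUDIT total")
  both <- !is.na(tab$audit_c_fu) & !is.na(tab$audit_total_fu)
  bad(both & tab$audit_c_fu > tab$audit_total_fu, "audit_c_fu",
      "AUDIT-C cannot exceed the AUDIT total")
  bad(!tab$completed %in% c(0L, 1L), "completed", "must be 0 or 1")
  bad(tab$completed == 1L & (is.na(tab$audit_total_fu) | is.na(tab$audit_c_fu)),
      "audit_total_fu", "follow-up scores must be present when completed=1")

  class(tab) <- c("trial_table", "data.frame")
  tab
}

#' Encode a trial table into a model design
#'
#' Performs the complete-case filtering and covariate coding the
#' hierarchical outcome models consume: rows without follow-up are dropped;
#' `Group` is 1 for the brief-intervention arm; `Sex` is 1 for the
#' non-reference sex (default reference `male`); education enters as two
#' dummies against the `incomplete` reference; age stays in raw years
#' unless `standardize_age`; the binary outcome is risky drinking at
#' follow-up, i.e. follow-up AUDIT total >= 8. For score outcomes the
#' matching baseline score is appended as a covariate. Center identifiers
#' are mapped to consecutive integers in first-appearance order.
#'
#' @param tab A validated trial table ([read_trial_csv()] /
#'   [validate_trial_table()]), or a `synthetic_trial`.
#' @param outcome One of `"risk"` (binary risky drinking), `"audit_total"`,
#'   `"audit_c"`.
#' @param sex_reference Reference sex level coded 0 (default `"male"`).
#' @param standardize_age If `TRUE`, z-score age over completers.
#' @return An object of class `encoded_design`: list with design matrix
#'   `X`, `center_index` (1..k), outcome vector `y`, binary indicator
#'   `y_binary`, completer count `n`, center count `k`, and bookkeeping.
#' @export
encode_design <- function(tab, outcome = c("risk", "audit_total", "audit_c"),
                          sex_reference = c("male", "female"),
                          standardize_age = FALSE) {
  outcome <- match.arg(outcome)
  sex_reference <- match.arg(sex_reference)
  if (inherits(tab, "synthetic_trial")) tab <- tab$table
  if (!inherits(tab, "trial_table")) tab <- validate_trial_table(tab)

  d <- tab[tab$completed == 1L, , drop = FALSE]
  if (nrow(d) == 0)
    stop("no completers: every row has completed=0", call. = FALSE)
  if (length(unique(d$arm)) < 2)
    stop("degenerate design: only one arm present among completers",
         call. = FALSE)

  age <- d$age
  if (standardize_age) age <- as.numeric(scale(age))
  X <- cbind(
    `(Intercept)` = 1,
    group = as.numeric(d$arm == "bi"),
    sex = as.numeric(d$sex != sex_reference),
    edu_complete = as.numeric(d$education == "complete"),
    edu_superior = as.numeric(d$education == "superior"),
    age = age
  )
  if (outcome == "audit_total") X <- cbind(X, baseline = d$audit_total_baseline)
  if (outcome == "audit_c") X <- cbind(X, baseline = d$audit_c_baseline)

  centers <- unique(d$center)
  y_binary <- as.integer(d$audit_total_fu >= 8L)
  y <- switch(outcome,
              risk = y_binary,
              audit_total = as.numeric(d$audit_total_fu),
              audit_c = as.numeric(d$audit_c_fu))

  structure(list(
    X = X,
    center_index = match(d$center, centers),
    y = y,
    y_binary = y_binary,
    outcome = outcome,
    n = nrow(d),
    k = length(centers),
    centers = centers,
    sex_reference = sex_reference,
    standardize_age = standardize_age,
    ids = d$id
  ), class = "encoded_design")
}

#' @export
print.encoded_design <- function(x, ...) {
  cat(sprintf("Encoded trial design: outcome %s, n = %d completers, k = %d centers, %d columns\n",
              x$outcome, x$n, x$k, ncol(x$X)))
  invisible(x)
}
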