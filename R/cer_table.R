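#' Average cost-effectiveness ratio of a cell
#'
#' The average cost-effectiveness ratio (CER) of one intervention cell versus
#' usual care is its per-participant net-present-value cost divided by its
#' per-participant QALY gain. Cells that both save costs and gain health
#' (`cost < 0`, `qaly > 0`) are flagged `"cost-saving"` (always worth funding);
#' cells with no positive health gain are flagged `"dominated"` (never funded)
#' and their ratio is `NA`.
#'
#' @param qaly,cost Per-participant QALY gain and cost (vectorized).
#' @return A tibble with columns `ratio` (euro per QALY), `rounded` (ratio
#'   rounded to the nearest 100 euro, the league-table reporting convention)
#'   and `status` (`"positive"`, `"cost-saving"` or `"dominated"`).
#' @export
#' @examples
#' average_cer(0.5, 700)  # 1400 euro per QALY
average_cer <- function(qaly, cost) {
  if (length(qaly) != length(cost)) stop("qaly and cost lengths differ", call. = FALSE)
  if (any(qaly == 0 & cost == 0)) {
    stop("degenerate cell: qaly and cost both zero", call. = FALSE)
  }
  status <- ifelse(qaly <= 0, "dominated",
                   ifelse(cost < 0, "cost-saving", "positive"))
  ratio <- ifelse(qaly > 0, cost / qaly, NA_real_)
  tibble(ratio = ratio, rounded = round_to_hundred(ratio), status = status)
}

round_to_hundred <- function(x) round(x / 100) * 100

#' League table of average cost-effectiveness ratios
#'
#' Builds a CER table from an [allocation_problem()] by recomputing each
#' cell's average ratio from its per-participant QALYs and costs.
#'
#' @param problem An [allocation_problem()] with per-cell outcomes set.
#' @return A `cer_table`: a tibble with columns `short_name`, `program_code`,
#'   `age_label`, `population`, `average_cer`, `status`.
#' @export
cer_table <- function(problem) {
  stopifnot(inherits(problem, "allocation_problem"))
  cl <- problem$cells
  if (anyNA(cl$qaly) || anyNA(cl$cost)) {
    stop("problem cells carry no (qaly, cost) outcomes; ",
         "league tables need a full problem (see fixture_problem())",
         call. = FALSE)
  }
  cer <- average_cer(cl$qaly, cl$cost)
  out <- tibble(
    short_name = cl$short_name,
    program_code = cl$code,
    age_label = cl$age_label,
    population = cl$population,
    average_cer = cer$ratio,
    status = cer$status
  )
  class(out) <- c("cer_table", class(out))
  out
}

#' The packaged league-table fixture
#'
#' Loads the packaged table of published average cost-per-QALY ratios for 12
#' cardiovascular/diabetes prevention programs in 3 age groups (euro, price
#' level 2007): smoking-cessation support (minimal and intensive), lifestyle
#' programs for overweight and physical activity, statins, and blood-pressure
#' medication, each for the general population and for diabetes patients.
#' Ratios are reported rounded to the nearest 100 euro.
#'
#' @return A `cer_table` of 36 rows.
#' @export
cer_fixture <- function() {
  path <- system.file("extdata", "cer_table_2007.csv", package = "prevalloc",
                      mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  out <- as_tibble(df)
  out$status <- "positive"
  class(out) <- c("cer_table", class(out))
  out
}

#' Rank a league table by ascending cost per QALY
#'
#' Stable ascending sort on the average ratio. Cost-saving rows sort first
#' (their ratios are negative); dominated rows are excluded with a notice;
#' ties are broken by program code then age label.
#'
#' @param table A `cer_table`.
#' @return The ranked `cer_table` (dominated rows removed).
#' @export
rank_by_cer <- function(table) {
  stopifnot(inherits(table, "cer_table") || is.data.frame(table))
  if (nrow(table) == 0) return(table)
  dominated <- !is.na(table$status) & table$status == "dominated"
  if (any(dominated)) {
    message("rank_by_cer: excluding ", sum(dominated), " dominated row(s): ",
            paste(table$short_name[dominated], collapse = ", "))
    table <- table[!dominated, ]
  }
  ord <- order(table$average_cer, table$program_code, table$age_label,
               method = "radix")
  table[ord, ]
}

#' Count league-table rows inside a cost-per-QALY band
#'
#' @param table A `cer_table`.
#' @param lower,upper Band limits in euro per QALY; both endpoints are
#'   exclusive. `upper` may be `Inf`.
#' @param population Optional population tag (`"general"` or `"diabetes"`) to
#'   restrict the count.
#' @return The number of rows with `lower < average_cer < upper`.
#' @export
count_by_cer_band <- function(table, lower, upper, population = NULL) {
  stopifnot(is.data.frame(table), lower < upper)
  if (!is.null(population)) {
    valid <- unique(table$population)
    if (!population %in% valid) {
      stop("unknown population tag '", population, "'; valid tags: ",
           paste(sort(valid), collapse = ", "), call. = FALSE)
    }
    table <- table[table$population == population, ]
  }
  ratio <- table$average_cer
  sum(!is.na(ratio) & ratio > lower & ratio < upper)
}
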