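#' Read an allocation problem from CSV or JSON
#'
#' The CSV dialect is UTF-8, comma-separated, header row required, decimal
#' point. Columns follow the flat cell schema of [allocation_problem()];
#' `capacity` accepts `"inf"` or an empty field for unbounded programs. The
#' JSON schema mirrors the problem components (`programs`, `age_groups`,
#' `cells`, `capacities`, `meta`) as written by [write_problem()].
#'
#' @param path Path to the file.
#' @param format `"csv"` or `"json"`; guessed from the file extension when
#'   omitted.
#' @return A validated [allocation_problem()].
#' @export
load_problem <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)

  if (format == "csv") {
    df <- tryCatch(
      utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8"),
      error = function(e) stop("failed to parse ", path, ": ",
                               conditionMessage(e), call. = FALSE)
    )
    problem <- allocation_problem(df)
  } else {
    obj <- tryCatch(
      jsonlite::read_json(path, simplifyVector = TRUE),
      error = function(e) stop("failed to parse ", path, ": ",
                               conditionMessage(e), call. = FALSE)
    )
    for (key in c("cells", "age_groups", "capacities")) {
      if (is.null(obj[[key]])) {
        stop("JSON problem file is missing key '", key, "'", call. = FALSE)
      }
    }
    cells <- as_tibble(obj$cells)
    caps <- obj$capacities
    cells$capacity <- caps$capacity[match(cells$program_code, caps$program_code)]
    cells$capacity[is.na(cells$capacity)] <- Inf
    starts <- stats::setNames(obj$age_groups$start_age, obj$age_groups$label)
    meta <- obj$meta
    if (!is.null(meta$discount)) {
      meta$discount <- discount_spec(meta$discount$rate_health,
                                     meta$discount$rate_cost,
                                     meta$discount$horizon)
    }
    problem <- allocation_problem(cells, start_ages = starts, meta = meta)
  }

  viol <- validate_problem(problem)
  if (length(viol) > 0) {
    stop("invalid allocation problem in ", path, ":\n  ",
         paste(viol, collapse = "\n  "), call. = FALSE)
  }
  problem
}

#' Write an allocation problem to CSV or JSON
#'
#' CSV writes the flat cell schema at full printed precision (15 significant
#' digits); JSON writes all components losslessly.
#'
#' @param problem An [allocation_problem()].
#' @param path Output path.
#' @param format `"csv"` or `"json"`; guessed from the extension when omitted.
#' @return `path`, invisibly.
#' @export
write_problem <- function(problem, path, format = c("auto", "csv", "json")) {
  stopifnot(inherits(problem, "allocation_problem"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "csv") {
    df <- problem_cells(problem)
    df$capacity <- ifelse(is.finite(df$capacity),
                          format(df$capacity, digits = 15, trim = TRUE,
                                 scientific = FALSE),
                          "inf")
    for (col in c("qaly_per_participant", "cost_per_participant", "demand")) {
      df[[col]] <- format(df[[col]], digits = 15, trim = TRUE, scientific = FALSE)
    }
    utils::write.csv(df, path, row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8")
  } else {
    meta <- problem$meta
    if (!is.null(meta$discount)) meta$discount <- unclass(meta$discount)
    obj <- list(
      programs = problem$programs,
      age_groups = problem$age_groups,
      cells = problem_cells(problem)[, c("program_code", "program_title",
                                         "population", "age_label",
                                         "qaly_per_participant",
                                         "cost_per_participant", "demand")],
      capacities = tibble(program_code = problem$capacities$code,
                          capacity = problem$capacities$capacity),
      meta = meta
    )
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                         na = "null", pretty = TRUE)
  }
  invisible(path)
}

#' Write an allocation (solution) to CSV or JSON
#'
#' The CSV holds the cell-level solution (participants, spend, QALYs); the
#' JSON additionally carries the solve status, binding constraints and dual
#' values (shadow prices). Monetary columns are euro at the problem's price
#' level.
#'
#' @param allocation An allocation returned by [solve_allocation()].
#' @param path Output path.
#' @param format `"csv"` or `"json"`; guessed from the extension when omitted.
#' @return `path`, invisibly.
#' @export
write_allocation <- function(allocation, path, format = c("auto", "csv", "json")) {
  stopifnot(inherits(allocation, "allocation"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "csv") {
    utils::write.csv(allocation$participants, path, row.names = FALSE,
                     fileEncoding = "UTF-8")
  } else {
    obj <- list(
      budget = allocation$budget,
      spend = allocation$spend,
      total_qalys = allocation$total_qalys,
      status = allocation$status,
      binding = allocation$binding,
      degenerate = allocation$degenerate,
      duals = allocation$duals,
      participants = allocation$participants
    )
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                         na = "null", pretty = TRUE)
  }
  invisible(path)
}
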