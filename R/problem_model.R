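#' @importFrom rlang .data
#' @import tibble
NULL

#' Build an allocation problem from a flat cell table
#'
#' An allocation problem is the full decision problem of preventive-care
#' priority setting: a set of programs (each targeting either the general
#' population or diagnosed diabetes patients), a set of age groups, one cell
#' per program x age group carrying per-participant net-present-value QALY
#' gains and healthcare costs versus usual care plus a demand limit (size of
#' the eligible target group), and a per-program capacity limit on total
#' participants across ages (professional supply).
#'
#' @param cells A data frame with one row per program x age-group cell and
#'   columns `program_code`, `program_title`, `population` (`"general"` or
#'   `"diabetes"`), `age_label`, `qaly_per_participant`,
#'   `cost_per_participant`, `demand`, `capacity`. `capacity` is repeated on
#'   every row of a program and may be `Inf` (or `NA`, read as unbounded).
#'   `qaly_per_participant`/`cost_per_participant` may be `NA` for league-table
#'   stubs that carry ratios only.
#' @param start_ages Optional named numeric vector mapping age labels to
#'   representative cohort entry ages. When missing, the numeric prefix of
#'   each label is used (e.g. 20 from `"20-44"`), falling back to rank order.
#' @param meta A list of problem metadata: `currency`, `price_year`,
#'   `discount` (a [discount_spec()]), `ref_population` (persons, for
#'   per-capita reporting), `demand_net_of_overlap` (flag asserting that
#'   general-population demands exclude diabetes patients, i.e. the two target
#'   populations are disjoint).
#'
#' @return An object of class `allocation_problem`: a list with tibbles
#'   `programs`, `age_groups`, `cells`, `capacities` and the `meta` list.
#'   Construction is permissive; use [validate_problem()] to list invariant
#'   violations.
#' @export
allocation_problem <- function(cells, start_ages = NULL, meta = list()) {
  cells <- as_tibble(cells)
  required <- c("program_code", "population", "age_label",
                "qaly_per_participant", "cost_per_participant",
                "demand", "capacity")
  missing_cols <- setdiff(required, names(cells))
  if (length(missing_cols) > 0) {
    stop("cell table is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!"program_title" %in% names(cells)) cells$program_title <- cells$program_code

  labels <- unique(cells$age_label)
  starts <- resolve_start_ages(labels, start_ages)
  age_groups <- tibble(
    age_id = seq_along(starts),
    label = names(starts),
    start_age = unname(starts)
  )

  prog_first <- which(!duplicated(cells$program_code))
  prog_first <- prog_first[order(cells$program_code[prog_first])]
  programs <- tibble(
    program_id = seq_along(prog_first),
    code = cells$program_code[prog_first],
    title = as.character(cells$program_title[prog_first]),
    population = as.character(cells$population[prog_first])
  )

  cap_raw <- cells$capacity
  cap_num <- suppressWarnings(as.numeric(ifelse(cap_raw %in% c("inf", "Inf", ""),
                                                Inf, cap_raw)))
  cap_num[is.na(cap_num)] <- Inf
  capacities <- tibble(
    program_id = programs$program_id,
    code = programs$code,
    capacity = cap_num[prog_first]
  )
  # capacity repeated per row must agree within each program
  for (i in seq_len(nrow(programs))) {
    vals <- cap_num[cells$program_code == programs$code[i]]
    if (length(unique(vals)) > 1) {
      stop("capacity differs across rows of program '", programs$code[i], "'",
           call. = FALSE)
    }
  }

  cell_tbl <- tibble(
    program_id = programs$program_id[match(cells$program_code, programs$code)],
    age_id = age_groups$age_id[match(cells$age_label, age_groups$label)],
    code = cells$program_code,
    age_label = cells$age_label,
    population = as.character(cells$population),
    qaly = as.numeric(cells$qaly_per_participant),
    cost = as.numeric(cells$cost_per_participant),
    demand = as.numeric(cells$demand)
  )
  cell_tbl$short_name <- paste0(cell_tbl$code, cell_tbl$age_id)
  cell_tbl <- cell_tbl[order(cell_tbl$code, cell_tbl$age_id), ]

  meta <- utils::modifyList(
    list(currency = "EUR", price_year = 2007,
         discount = NULL, ref_population = NULL,
         demand_net_of_overlap = TRUE),
    meta
  )

  structure(
    list(programs = programs, age_groups = age_groups,
         cells = cell_tbl, capacities = capacities, meta = meta),
    class = "allocation_problem"
  )
}

resolve_start_ages <- function(labels, start_ages = NULL) {
  if (!is.null(start_ages)) {
    if (!all(labels %in% names(start_ages))) {
      stop("start_ages must name every age label", call. = FALSE)
    }
    s <- start_ages[labels]
  } else {
    prefix <- suppressWarnings(as.numeric(sub("^([0-9]+).*$", "\\1", labels)))
    s <- if (anyNA(prefix)) stats::setNames(seq_along(labels), labels) else
      stats::setNames(prefix, labels)
  }
  sort(vapply(s, as.numeric, numeric(1)))
}

#' @export
print.allocation_problem <- function(x, ...) {
  cat("<allocation_problem> ", nrow(x$programs), " programs x ",
      nrow(x$age_groups), " age groups (", nrow(x$cells), " cells)\n", sep = "")
  n_cap <- sum(is.finite(x$capacities$capacity))
  cat("  populations: ",
      paste(sprintf("%s (%d)", names(table(x$programs$population)),
                    table(x$programs$population)), collapse = ", "), "\n", sep = "")
  cat("  finite capacities: ", n_cap, "/", nrow(x$capacities), "\n", sep = "")
  if (all(is.finite(x$cells$qaly))) {
    cat("  total demand-limited QALY potential: ",
        format(sum(pmax(x$cells$qaly, 0) * x$cells$demand), big.mark = ","),
        "\n", sep = "")
  } else {
    cat("  per-cell outcomes not set (league-table stub)\n")
  }
  invisible(x)
}

#' Flatten an allocation problem back to the tidy cell schema
#'
#' @param problem An [allocation_problem()].
#' @return A tibble in the flat cell schema accepted by [allocation_problem()]
#'   and written by [write_problem()].
#' @export
problem_cells <- function(problem) {
  stopifnot(inherits(problem, "allocation_problem"))
  cl <- problem$cells
  tibble(
    program_code = cl$code,
    program_title = problem$programs$title[match(cl$program_id,
                                                 problem$programs$program_id)],
    population = cl$population,
    age_label = cl$age_label,
    qaly_per_participant = cl$qaly,
    cost_per_participant = cl$cost,
    demand = cl$demand,
    capacity = problem$capacities$capacity[match(cl$program_id,
                                                 problem$capacities$program_id)]
  )
}

#' List invariant violations of an allocation problem
#'
#' Checks the structural invariants of the decision problem: complete and
#' unique program x age coverage, non-negative demands and capacities, finite
#' per-cell outcomes, unique codes and labels, strictly increasing
#' representative start ages, known population tags, and the disjointness
#' assumption that general-population demands are declared net of diabetes
#' patients (diabetes-specific programs take priority where target groups
#' overlap).
#'
#' @param problem An [allocation_problem()].
#' @return A character vector of human-readable violations; empty when all
#'   invariants hold. Violations are returned, never raised.
#' @export
validate_problem <- function(problem) {
  v <- character(0)
  if (!inherits(problem, "allocation_problem")) {
    return("not an allocation_problem object")
  }
  pr <- problem$programs; ag <- problem$age_groups
  cl <- problem$cells; cp <- problem$capacities

  if (anyDuplicated(pr$code)) v <- c(v, "duplicate program codes")
  if (anyDuplicated(ag$label)) v <- c(v, "duplicate age labels")
  if (is.unsorted(ag$start_age, strictly = TRUE)) {
    v <- c(v, "age-group start ages not strictly increasing")
  }
  bad_pop <- setdiff(unique(pr$population), c("general", "diabetes"))
  if (length(bad_pop) > 0) {
    v <- c(v, paste0("unknown population tag(s): ", paste(bad_pop, collapse = ", ")))
  }

  key <- paste(cl$program_id, cl$age_id)
  dup <- unique(key[duplicated(key)])
  for (k in dup) {
    i <- match(k, key)
    v <- c(v, paste0("duplicate cell for (", cl$code[i], ", ", cl$age_label[i], ")"))
  }
  expected <- expand.grid(program_id = pr$program_id, age_id = ag$age_id)
  miss <- !paste(expected$program_id, expected$age_id) %in% key
  for (i in which(miss)) {
    v <- c(v, paste0("missing cell for (", pr$code[pr$program_id == expected$program_id[i]],
                     ", ", ag$label[ag$age_id == expected$age_id[i]], ")"))
  }

  if (any(!is.na(cl$demand) & cl$demand < 0)) {
    bad <- cl$short_name[!is.na(cl$demand) & cl$demand < 0]
    v <- c(v, paste0("negative demand in cell(s): ", paste(bad, collapse = ", ")))
  }
  if (any(!is.na(cl$qaly) & !is.finite(cl$qaly)) ||
      any(!is.na(cl$cost) & !is.finite(cl$cost))) {
    v <- c(v, "non-finite qaly or cost values")
  }
  bad_cap <- cp$code[!is.na(cp$capacity) & cp$capacity < 0]
  for (code in bad_cap) {
    v <- c(v, paste0("negative capacity for program ", code))
  }
  if (!isTRUE(problem$meta$demand_net_of_overlap)) {
    v <- c(v, paste0("meta$demand_net_of_overlap is not TRUE: general-population ",
                     "demands must be declared net of diabetes patients ",
                     "(disjoint target populations)"))
  }
  v
}

#' Assemble a demonstration problem from the packaged league-table fixture
#'
#' The packaged cost-effectiveness fixture carries average cost-per-QALY
#' ratios only, not per-participant QALYs and costs separately. For
#' end-to-end demonstrations this helper fixes the per-participant QALY gain
#' per age group at documented constants and derives per-participant cost as
#' ratio x QALY gain, then attaches synthetic demand and capacity limits
#' (general-population target groups an order of magnitude larger than
#' diabetes target groups; capacity a fixed fraction of each program's total
#' demand). All quantities other than the ratios are illustrative constants,
#' not study data.
#'
#' @param qaly_by_age Named QALY gains per participant by age label.
#'   Defaults: 0.50 (20-44), 0.35 (45-64), 0.20 (65+).
#' @param demand_general,demand_diabetes Demands per age group (persons).
#' @param capacity_share Capacity as a fraction of each program's total
#'   demand (default 0.6).
#' @return An [allocation_problem()] whose per-cell average cost-per-QALY
#'   ratios reproduce the packaged fixture exactly.
#' @export
fixture_problem <- function(qaly_by_age = c("20-44" = 0.50, "45-64" = 0.35, "65+" = 0.20),
                            demand_general = c("20-44" = 200000, "45-64" = 150000, "65+" = 80000),
                            demand_diabetes = c("20-44" = 15000, "45-64" = 45000, "65+" = 35000),
                            capacity_share = 0.6) {
  fx <- cer_fixture()
  q <- unname(qaly_by_age[fx$age_label])
  dem <- ifelse(fx$population == "general",
                unname(demand_general[fx$age_label]),
                unname(demand_diabetes[fx$age_label]))
  cells <- tibble(
    program_code = fx$program_code,
    program_title = fx$program_title,
    population = fx$population,
    age_label = fx$age_label,
    qaly_per_participant = q,
    cost_per_participant = fx$average_cer * q,
    demand = dem,
    capacity = NA_real_
  )
  prog_dem <- tapply(cells$demand, cells$program_code, sum)
  cells$capacity <- capacity_share * unname(prog_dem[cells$program_code])
  allocation_problem(
    cells,
    start_ages = c("20-44" = 32, "45-64" = 55, "65+" = 72),
    meta = list(discount = discount_spec(), ref_population = 16.4e6)
  )
}
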