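# File formats:
#   calcium trace CSV  — header `time_s,ca_cyt_nM`, optional comment line
#                        `# thapsigargin_time_s=<float>`
#   dose-response CSV  — header `lactate_mM,ca_ss_nM,sem_nM`
#   parameter sets     — flat JSON with the constructor field names

#' Path to a packaged reference fixture
#'
#' The package ships the printed reference tables as plain-text fixtures:
#' `table1_lactate_pre.csv`, `table1_lactate_post.csv` (lactate
#' dose-responses), `table2_dynamic_fits.csv` (the 15 per-experiment fitted
#' parameter sets), `table3_initial_params.json` (the shared fitting start
#' values), `table4_cell.json` (cell geometry and physical constants),
#' `table5_steady_state_pre.json`, `table5_steady_state_post.json` (fitted
#' steady-state parameter sets) and `table5_initial_values.json`.
#'
#' @param name fixture file name; with no argument, lists available names.
#' @return Full path (or a character vector of names).
#' @export
spermca_fixture <- function(name = NULL) {
  dir <- system.file("extdata", package = "spermCa", mustWork = TRUE)
  if (is.null(name)) return(list.files(dir))
  path <- file.path(dir, name)
  if (!file.exists(path)) stop("no packaged fixture named '", name, "'")
  path
}

#' Read a calcium trace CSV
#'
#' @param path CSV with header `time_s,ca_cyt_nM`; an optional comment line
#'   `# thapsigargin_time_s=<float>` carries the event time.
#' @return A [calcium_trace()].
#' @export
load_trace <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L) stop("trace file too short")
  thaps <- NULL
  cm <- grep("^#", lines, value = TRUE)
  ev <- grep("^#\\s*thapsigargin_time_s=", cm, value = TRUE)
  if (length(ev)) {
    thaps <- suppressWarnings(as.numeric(sub("^#\\s*thapsigargin_time_s=", "",
                                             ev[1])))
    if (is.na(thaps)) stop("malformed thapsigargin_time_s comment line")
  }
  df <- read.csv(text = lines[!grepl("^#", lines)])
  if (!all(c("time_s", "ca_cyt_nM") %in% names(df)))
    stop("malformed header: expected columns time_s, ca_cyt_nM")
  if (anyNA(df$time_s) || anyNA(df$ca_cyt_nM))
    stop("NaN/NA values in trace file")
  if (any(diff(df$time_s) <= 0))
    stop("non-monotone time column")
  calcium_trace(df$time_s, df$ca_cyt_nM, thapsigargin_time = thaps)
}

#' Write a calcium trace CSV
#'
#' @param trace a [calcium_trace()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "calcium_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(trace$thapsigargin_time))
    writeLines(sprintf("# thapsigargin_time_s=%.17g",
                       trace$thapsigargin_time), con)
  writeLines("time_s,ca_cyt_nM", con)
  writeLines(sprintf("%.17g,%.17g", trace$t, trace$ca_cyt), con)
  invisible(path)
}

#' Read a lactate dose-response CSV
#'
#' @param path CSV with header `lactate_mM,ca_ss_nM,sem_nM` (`sem_nM`
#'   optional).
#' @return A [lactate_response()].
#' @export
load_lactate_response <- function(path) {
  df <- read.csv(path)
  if (!all(c("lactate_mM", "ca_ss_nM") %in% names(df)))
    stop("malformed header: expected columns lactate_mM, ca_ss_nM")
  lactate_response(df$lactate_mM, df$ca_ss_nM,
                   sem = if ("sem_nM" %in% names(df)) df$sem_nM)
}

#' Write a lactate dose-response CSV
#'
#' @param data a [lactate_response()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_lactate_response <- function(data, path) {
  stopifnot(inherits(data, "lactate_response"))
  out <- data.frame(lactate_mM = data$l, ca_ss_nM = data$ca_ss,
                    sem_nM = data$sem)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a parameter set from flat JSON
#'
#' Dispatches on the field names: the five reduced-model constants give a
#' [reduced_params()], the steady-state fields a [steady_state_params()].
#'
#' @param path JSON file.
#' @return A parameter object.
#' @export
load_params <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (all(c("delta", "phi", "omega", "k_l", "b") %in% names(x)))
    return(steady_state_params(x$delta, x$phi, x$omega, x$k_l, x$b,
                               with_thapsigargin = isTRUE(x$with_thapsigargin)))
  if (all(c("p", "q", "r", "d", "g") %in% names(x)))
    return(reduced_params(x$p, x$q, x$r, x$d, x$g))
  stop("unrecognised parameter JSON: ", path)
}

#' Write a parameter set to flat JSON
#'
#' @param params a [reduced_params()] or [steady_state_params()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "reduced_params") ||
              inherits(params, "steady_state_params"))
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Packaged reference tables
#'
#' Convenience loaders for the packaged fixtures (see [spermca_fixture()]).
#' `fixture_table1()` returns the pre/post dose-responses,
#' `fixture_table2()` the 15 fitted dynamic parameter sets (data.frame plus
#' a `params` list column-free accessor), `fixture_table3_initial()` the
#' shared fitting start values, `fixture_table4()` the cell geometry,
#' physical constants and characteristic concentrations, and
#' `fixture_table5()` a fitted steady-state parameter set.
#'
#' @return See each description.
#' @name fixtures
NULL

#' @rdname fixtures
#' @export
fixture_table1 <- function() {
  list(pre = load_lactate_response(spermca_fixture("table1_lactate_pre.csv")),
       post = load_lactate_response(spermca_fixture("table1_lactate_post.csv")))
}

#' @rdname fixtures
#' @export
fixture_table2 <- function() {
  df <- read.csv(spermca_fixture("table2_dynamic_fits.csv"))
  attr(df, "params") <- lapply(seq_len(nrow(df)), function(i)
    reduced_params(df$p[i], df$q[i], df$r[i], df$d[i], df$g[i]))
  df
}

#' @rdname fixtures
#' @export
fixture_table3_initial <- function() {
  load_params(spermca_fixture("table3_initial_params.json"))
}

#' @rdname fixtures
#' @export
fixture_table4 <- function() {
  x <- jsonlite::read_json(spermca_fixture("table4_cell.json"),
                           simplifyVector = TRUE)
  list(geometry = do.call(cell_geometry, x$geometry),
       physical = physical_params(p_leak1 = x$physical$p_leak1,
                                  p_leak2 = x$physical$p_leak2,
                                  k3_prime = x$physical$k3_prime,
                                  km_atp = x$physical$km_atp),
       characteristic = x$characteristic)
}

#' @rdname fixtures
#' @param condition `"pre"` (without thapsigargin), `"post"` (with) or
#'   `"init"` (the fitting start values, flag unset).
#' @export
fixture_table5 <- function(condition = c("pre", "post", "init")) {
  condition <- match.arg(condition)
  file <- switch(condition,
                 pre = "table5_steady_state_pre.json",
                 post = "table5_steady_state_post.json",
                 init = "table5_initial_values.json")
  x <- jsonlite::read_json(spermca_fixture(file), simplifyVector = TRUE)
  steady_state_params(x$delta, x$phi, x$omega, x$k_l, x$b,
                      with_thapsigargin = isTRUE(x$with_thapsigargin))
}

#' Recompute the headline reference numbers from packaged fixtures
#'
#' Runs the package end to end on the packaged reference tables and checks
#' each recomputed quantity against its printed value: cohort aggregates of
#' the 15 dynamic fits (means, CV% of `p`, mean/initial ratio of `g`), the
#' geometric composition of `g`, the dose-response R^2 of both steady-state
#' curves, the pump-activity ratio and constitutive-ATP drop, and the
#' analytic stationary calcium of the mean dynamic parameters.
#'
#' @return A `reproduction_report` data.frame with columns `target`,
#'   `computed`, `expected`, `tol` (comparison rule) and `pass`; attribute
#'   `passed` is `TRUE` when every row passes.
#' @export
reproduce_reference <- function() {
  t1 <- fixture_table1()
  t2 <- fixture_table2()
  init <- fixture_table3_initial()
  cell <- fixture_table4()
  ss_pre <- fixture_table5("pre")
  ss_post <- fixture_table5("post")

  summ <- summarize_fits(attr(t2, "params"), init)
  gmap <- map_physical_to_reduced(cell$geometry, cell$physical)$g
  r2_pre <- r_squared(t1$pre$ca_ss, predict_curve(ss_pre, t1$pre$l))
  r2_post <- r_squared(t1$post$ca_ss, predict_curve(ss_post, t1$post$l))
  cmp <- compare_conditions(ss_pre, ss_post)
  mean_pars <- reduced_params(summ["p", "mean"], summ["q", "mean"],
                              summ["r", "mean"], summ["d", "mean"],
                              summ["g", "mean"])
  ca_ss <- reduced_steady_state(mean_pars)

  rows <- list(
    list("mean p [nM/s]",         summ["p", "mean"], 2.47e-1, "rel 1%"),
    list("mean r [1/s]",          summ["r", "mean"], 6.27e-5, "rel 1%"),
    list("mean d [1/(nM s)]",     summ["d", "mean"], 2.31e-5, "rel 1%"),
    list("mean g [1/s]",          summ["g", "mean"], 3.38e-3, "rel 1%"),
    list("CV% of p",              summ["p", "cv_percent"], 82, "round 0"),
    list("mean(g)/initial(g)",    summ["g", "ratio_to_initial"], 1.21, "round 2"),
    list("g from geometry [1/s]", gmap, 2.80e-3, "rel 2%"),
    list("R^2 dose-response, no thapsigargin", r2_pre, 0.98, "round 2"),
    list("R^2 dose-response, thapsigargin",    r2_post, 0.98, "round 2"),
    list("pump activity ratio (delta'-delta)/delta", cmp$pump_ratio, 17, "round 0"),
    list("phi decrease fraction", cmp$phi_change_fraction, 0.24, "round 2"),
    list("stationary [Ca2+]cyt of mean params [nM]", ca_ss, 100, "ge"))

  check <- function(computed, expected, tol) {
    switch(sub(" .*", "", tol),
           rel = abs(computed - expected) <=
             as.numeric(sub(".*rel ([0-9.]+)%.*", "\\1", tol)) / 100 * abs(expected),
           round = round(computed, as.integer(sub(".*round ", "", tol))) ==
             expected,
           ge = computed >= expected)
  }
  rep <- data.frame(
    target = vapply(rows, `[[`, character(1), 1),
    computed = vapply(rows, `[[`, numeric(1), 2),
    expected = vapply(rows, `[[`, numeric(1), 3),
    tol = vapply(rows, `[[`, character(1), 4))
  rep$pass <- mapply(check, rep$computed, rep$expected, rep$tol)
  attr(rep, "passed") <- all(rep$pass)
  class(rep) <- c("reproduction_report", "data.frame")
  rep
}

#' @export
print.reproduction_report <- function(x, ...) {
  df <- as.data.frame(x)
  df$computed <- signif(df$computed, 5)
  df$pass <- ifelse(df$pass, "PASS", "FAIL")
  print(df, row.names = FALSE)
  cat(if (attr(x, "passed")) "\nAll targets reproduced.\n"
      else "\nSome targets FAILED.\n")
  invisible(x)
}
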