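#' Write a complete model workspace to disk
#'
#' Emits every input the pipeline needs as plain text: the parameter
#' table (`parameters.csv`), the life table (`life_table.csv`), the
#' population profiles (`populations.json`) and a run manifest
#' (`manifest.json`) recording the seed, file digests, package version
#' and timestamp.  The written files round-trip bit-identically through
#' [load_workspace()].
#'
#' @param dir Output directory (created if needed).
#' @param seed Seed handed to [gen_life_table()].
#' @param params Optional [parameter_set()]; defaults to
#'   [gen_default_parameters()].
#' @param populations Population names to include.
#' @return `dir`, invisibly.
#' @export
write_workspace <- function(dir, seed = 1L, params = NULL,
                            populations = c("PEACE", "SuValue_100",
                                            "SuValue_70", "BERSON",
                                            "FOURIER")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(params)) params <- gen_default_parameters()
  lt <- gen_life_table(seed)
  f_par <- file.path(dir, "parameters.csv")
  f_lt <- file.path(dir, "life_table.csv")
  f_pop <- file.path(dir, "populations.json")
  # numeric columns are written at full double precision (%.17g) so a
  # load/save cycle reproduces the files bit-identically
  fmt <- function(df) {
    for (j in seq_along(df))
      if (is.numeric(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
    df
  }
  utils::write.csv(fmt(as.data.frame(params)), f_par, row.names = FALSE,
                   quote = TRUE)
  utils::write.csv(fmt(as.data.frame(lt)), f_lt, row.names = FALSE,
                   quote = TRUE)
  pops <- lapply(populations, function(nm) {
    p <- gen_population(nm)
    p[!vapply(p, is.null, logical(1))]
  })
  writeLines(jsonlite::toJSON(pops, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA), f_pop)
  manifest <- list(
    seed = seed,
    package_version = as.character(utils::packageVersion("evocea")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    digests = as.list(tools::md5sum(c(f_par, f_lt, f_pop))))
  names(manifest$digests) <- basename(names(manifest$digests))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE),
             file.path(dir, "manifest.json"))
  invisible(dir)
}

#' Load and validate a model workspace
#'
#' Reads the parameter table, life table and population profiles written
#' by [write_workspace()], enforces every model invariant (utility
#' bounds, rate signs, mortality consistency, life-table monotonicity)
#' and cross-references the inputs against the state space.  Errors name
#' the file and the offending row.
#'
#' @param dir Workspace directory.
#' @param check_digests Verify file digests against the manifest when one
#'   is present.
#' @return List with `params`, `life_table`, `populations` (named list of
#'   profiles) and `manifest` (or `NULL`).
#' @export
load_workspace <- function(dir, check_digests = TRUE) {
  f_par <- file.path(dir, "parameters.csv")
  f_lt <- file.path(dir, "life_table.csv")
  f_pop <- file.path(dir, "populations.json")
  for (f in c(f_par, f_lt, f_pop))
    if (!file.exists(f)) stop("missing workspace file: ", f)
  manifest <- NULL
  f_man <- file.path(dir, "manifest.json")
  if (file.exists(f_man)) {
    manifest <- jsonlite::fromJSON(f_man)
    if (check_digests) {
      for (f in c(f_par, f_lt, f_pop)) {
        want <- manifest$digests[[basename(f)]]
        if (!is.null(want) && !identical(unname(tools::md5sum(f)), want))
          stop("digest mismatch for ", basename(f),
               ": workspace differs from its manifest")
      }
    }
  }
  pdf_ <- utils::read.csv(f_par, stringsAsFactors = FALSE)
  params <- validate_parameters(parameter_set(pdf_))
  ltd <- utils::read.csv(f_lt, stringsAsFactors = FALSE)
  lt <- tryCatch(life_table(ltd$age, ltd$all_cause_prob, ltd$cv_fraction),
                 error = function(e) stop("life_table.csv: ",
                                          conditionMessage(e), call. = FALSE))
  pops_raw <- jsonlite::fromJSON(f_pop, simplifyVector = FALSE)
  pops <- lapply(pops_raw, function(p) {
    prof <- gen_population(p$name, baseline_LDL = p$baseline_LDL)
    if (!is.null(p$start_age)) prof$start_age <- p$start_age
    prof
  })
  names(pops) <- vapply(pops, `[[`, character(1), "name")
  # cross-reference: every state must resolve a cost and a utility
  space <- build_state_space()
  invisible(state_costs(space, params, "healthcare"))
  invisible(state_utilities(space, params))
  for (p in pops) {
    if (!p$start_age %in% lt$age)
      stop("population '", p$name, "': start age ", p$start_age,
           " outside life-table support")
  }
  list(params = params, life_table = lt, populations = pops,
       manifest = manifest)
}
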