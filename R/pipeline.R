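#' @title Pipeline configuration, execution and report rendering
#' @name cli_report
#' @description Ties the modules together: build crystals of a list of
#'   sizes, assign parameters, decompose energies over the central chains,
#'   fit bulk energies, detect and score hydrogen bonds, and render the
#'   polymorph-comparison report in CSV, JSON or markdown.  A thin
#'   command-line wrapper over these functions ships in
#'   \code{inst/scripts/cellenergy-cli.R}.
NULL

#' Default run configuration
#'
#' @return Named list with the tunable parameters of a pipeline run: the
#'   polymorphs to compare, force-field variant, crystal sizes, number of
#'   central chains, hydrogen-bond criteria and scoring modes, seed and
#'   report formats.
#' @export
default_run_config <- function() {
  list(forms = c("Ibeta", "II"),
       variant = "GLYCAM06",
       n_chains = 12,
       dp_list = c(4, 6, 8),
       n_central = 4,
       criteria = list(max_d_HO = 3.0, min_angle = 115),
       hbond_modes = c("COH_O", "COH_COX"),
       seed = 1L,
       report_formats = c("csv", "json"))
}

#' Validate a run configuration
#'
#' @param config Named list; missing entries are filled from
#'   \code{\link{default_run_config}}.
#' @return The completed, validated configuration.
#' @export
validate_run_config <- function(config = list()) {
  def <- default_run_config()
  unknown <- setdiff(names(config), names(def))
  if (length(unknown) > 0)
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(def, config)
  if (!all(cfg$forms %in% c("Ibeta", "II")))
    stop("forms must be a subset of {Ibeta, II}")
  if (!cfg$variant %in% FF_VARIANTS)
    stop("unknown force-field variant: ", cfg$variant,
         " (expected one of ", paste(FF_VARIANTS, collapse = ", "), ")")
  if (any(cfg$dp_list < 2)) stop("all dp values must be >= 2")
  if (length(cfg$dp_list) < 2) stop("dp_list needs >= 2 sizes for bulk fits")
  if (cfg$n_central < 1 || cfg$n_central > cfg$n_chains)
    stop("n_central must be between 1 and n_chains")
  if (!all(cfg$hbond_modes %in% c("OH_O", "COH_O", "COH_COX")))
    stop("unknown hbond mode(s)")
  if (cfg$criteria$max_d_HO <= 0 || cfg$criteria$min_angle < 0 ||
      cfg$criteria$min_angle > 180)
    stop("invalid hydrogen-bond criteria")
  cfg
}

#' Read a run configuration from a YAML file
#'
#' @param path YAML file; top-level keys as in
#'   \code{\link{default_run_config}}.
#' @return Validated configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  validate_run_config(yaml::read_yaml(path))
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' For each requested polymorph: builds crystals at every chain length of
#' the size series, assigns and terminal-neutralizes charges, computes
#' interchain and intrachain nonbonded energies averaged over the central
#' chains, fits the bulk energies per glucose unit, detects hydrogen bonds
#' in the largest crystal, scores them in the configured modes, aggregates
#' interchain hydrogen-bond energies per glucose unit and reports them as a
#' fraction of the bulk interchain electrostatics.  Identical configurations
#' produce identical bundles.
#'
#' @param config Run configuration (list; validated with
#'   \code{\link{validate_run_config}}).
#' @param quiet Suppress stage logging.
#' @return A \code{report_bundle}: list with the echoed config and one
#'   result set per form.
#' @export
run_pipeline <- function(config = list(), quiet = FALSE) {
  cfg <- validate_run_config(config)
  say <- function(...) if (!quiet) message(...)
  ff <- .stage("forcefield", load_forcefield(cfg$variant))
  results <- list()
  for (form in cfg$forms) {
    say("[", form, "] building ", length(cfg$dp_list), " crystals of ",
        cfg$n_chains, " chains (dp ", paste(cfg$dp_list, collapse = ","),
        "), variant ", cfg$variant)
    inter_reports <- list()
    intra_reports <- list()
    biggest <- NULL
    for (dp in sort(cfg$dp_list)) {
      pc <- .stage(paste0("build/", form, "/dp", dp), {
        cr <- build_crystal(form, cfg$n_chains, dp)
        cr$central_chain_ids <- select_central_chains(cr, cfg$n_central)
        neutralize_termini(assign_parameters(cr, ff))
      })
      say("  dp ", dp, ": ", nrow(pc$atoms), " atoms, central chains ",
          paste(pc$central_chain_ids, collapse = ""))
      inter_reports[[as.character(dp)]] <-
        .stage("interchain_energy", interchain_energy(pc))
      intra_reports[[as.character(dp)]] <-
        .stage("intrachain_energy", intrachain_nonbonded_energy(pc))
      biggest <- pc
    }
    fits <- list()
    for (term in c("electrostatic", "vdw")) {
      fits[[paste0("interchain_", term)]] <-
        fit_bulk_energy(assemble_size_series(inter_reports, term))
      fits[[paste0("intrachain_nonbonded_", term)]] <-
        fit_bulk_energy(assemble_size_series(intra_reports, term))
    }
    hb <- .stage("hbond_detection",
                 detect_hbonds(biggest, cfg$criteria$max_d_HO,
                               cfg$criteria$min_angle))
    say("  hydrogen bonds detected (dp ", max(cfg$dp_list), "): ", nrow(hb))
    hb_modes <- list()
    per_glucose <- list()
    fractions <- list()
    for (mode in cfg$hbond_modes) {
      scored <- .stage(paste0("hbond_energy/", mode),
                       hbond_energy(biggest, hb, mode))
      hb_modes[[mode]] <- scored
      pg <- if (nrow(scored) > 0 &&
                all(scored$donor_parity %in% c("origin", "center")))
        aggregate_per_glucose(scored, "inter") else NA_real_
      per_glucose[[mode]] <- pg
      bulk_el <- fits$interchain_electrostatic$slope
      fractions[[mode]] <- if (is.finite(pg) && bulk_el != 0)
        fraction_of_interchain_electrostatics(pg, bulk_el) else NA_real_
    }
    results[[form]] <- list(bulk_fits = fits, hbonds = hb_modes,
                            hbond_per_glucose = per_glucose,
                            hbond_fraction_of_elec = fractions,
                            n_hbonds = nrow(hb))
  }
  structure(list(config = cfg, results = results), class = "report_bundle")
}

#' Render a report bundle to files
#'
#' CSV and markdown tables print energies to one decimal in kcal/mol
#' (geometry to two decimals); the JSON report retains full precision and
#' round-trips losslessly.
#'
#' @param bundle A \code{report_bundle} from \code{\link{run_pipeline}}.
#' @param format \code{"csv"}, \code{"json"} or \code{"markdown"}.
#' @param dir Output directory (created if needed).
#' @return Character vector of the files written, invisibly.
#' @export
render_report <- function(bundle, format = c("csv", "json", "markdown"),
                          dir = ".") {
  format <- match.arg(format)
  stopifnot(inherits(bundle, "report_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)
  if (format == "json") {
    path <- file.path(dir, "report.json")
    out <- list(config = bundle$config,
                results = lapply(bundle$results, .bundle_form_json))
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    return(invisible(path))
  }
  fits <- .bulk_fit_table(bundle)
  hbt <- .hbond_report_table(bundle)
  if (format == "csv") {
    f1 <- file.path(dir, "bulk_fits.csv")
    utils::write.csv(fits, f1, row.names = FALSE)
    f2 <- file.path(dir, "hbonds.csv")
    utils::write.csv(hbt, f2, row.names = FALSE)
    files <- c(f1, f2)
  } else {
    path <- file.path(dir, "report.md")
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("# Cellulose nonbonded energy report", "",
                 paste0("Variant: ", bundle$config$variant,
                        "; criteria: d_HO <= ",
                        bundle$config$criteria$max_d_HO,
                        " A, angle >= ", bundle$config$criteria$min_angle,
                        " deg"), "",
                 "## Bulk energies per glucose unit (kcal/mol)", "",
                 .md_table(fits), "",
                 "## Hydrogen bonds (class means)", "",
                 .md_table(hbt)), con)
    files <- path
  }
  invisible(files)
}

.bundle_form_json <- function(res) {
  list(bulk_fits = lapply(res$bulk_fits, unclass),
       hbond_per_glucose = res$hbond_per_glucose,
       hbond_fraction_of_elec = res$hbond_fraction_of_elec,
       n_hbonds = res$n_hbonds,
       hbond_classes = lapply(res$hbonds, function(h)
         if (nrow(h) == 0) list() else
           stats::aggregate(cbind(d_HO, d_OO, angle, electrostatic, vdw) ~
                              class_label, data = h, FUN = mean)))
}

.bulk_fit_table <- function(bundle) {
  rows <- list()
  for (form in names(bundle$results)) {
    fits <- bundle$results[[form]]$bulk_fits
    for (nm in names(fits)) {
      f <- fits[[nm]]
      rows[[length(rows) + 1L]] <- data.frame(
        form = form, term = nm,
        bulk_per_glucose = round(f$slope, 1),
        intercept = round(f$intercept, 1),
        slope_stderr = round(f$slope_stderr, 2),
        r_squared = round(f$r_squared, 4), stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0)
    return(data.frame(form = character(0), term = character(0),
                      bulk_per_glucose = numeric(0), intercept = numeric(0),
                      slope_stderr = numeric(0), r_squared = numeric(0)))
  do.call(rbind, rows)
}

.hbond_report_table <- function(bundle) {
  rows <- list()
  for (form in names(bundle$results)) {
    for (mode in names(bundle$results[[form]]$hbonds)) {
      h <- bundle$results[[form]]$hbonds[[mode]]
      if (nrow(h) == 0) next
      agg <- stats::aggregate(cbind(d_HO, d_OO, angle, electrostatic, vdw) ~
                                class_label, data = h, FUN = mean)
      rows[[length(rows) + 1L]] <- data.frame(
        form = form, mode = mode, class = agg$class_label,
        d_HO = round(agg$d_HO, 2), d_OO = round(agg$d_OO, 2),
        angle = round(agg$angle, 0),
        electrostatic = round(agg$electrostatic, 1),
        vdw = round(agg$vdw, 1), stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0)
    return(data.frame(form = character(0), mode = character(0),
                      class = character(0), d_HO = numeric(0),
                      d_OO = numeric(0), angle = numeric(0),
                      electrostatic = numeric(0), vdw = numeric(0)))
  do.call(rbind, rows)
}

.md_table <- function(df) {
  if (nrow(df) == 0) return(paste0("| ", paste(names(df), collapse = " | "),
                                   " |"))
  hdr <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- apply(df, 1, function(r)
    paste0("| ", paste(trimws(as.character(r)), collapse = " | "), " |"))
  c(hdr, sep, body)
}
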