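# Scenario comparison tables in the layout of published OCS studies:
# one row per scenario with the achieved mean kinships, migrant
# contribution, breeding value, selected-sire fraction and contribution
# spread, plus markers for bounds satisfied with slack.

#' Summarize scenario results into a comparison table
#'
#' @param results list of `nocs_result` objects (e.g. from [run_ocs()]).
#' @param bounds optional named list of bound values used across the
#'   scenarios; constrained cells whose achieved value stays clear of the
#'   bound by more than `slack_tol` are flagged slack.
#' @param slack_tol slack-flag tolerance; the default is ten times the
#'   solver feasibility tolerance, separating numerical grazing of a bound
#'   from genuine slack.
#' @return an object of class `nocs_table`: a data frame with columns
#'   `scenario`, `status`, `fA`, `fB`, `fC`, `fD`, `MC`, `EBV`,
#'   `selected`, `sd_cs`, carrying a `slack` attribute (named list of
#'   per-scenario flags: `"active"` or `"slack"` per constrained
#'   criterion). Values are kept at full precision; rounding is applied by
#'   the print method only.
#' @export
summarize_scenarios <- function(results, bounds = NULL, slack_tol = 1e-5) {
  stopifnot(length(results) >= 1L)
  if (is.null(names(results))) {
    names(results) <- vapply(results, `[[`, character(1), "name")
  }
  rows <- lapply(names(results), function(nm) {
    r <- results[[nm]]
    data.frame(scenario = r$name, status = r$solver_status,
               fA = r$achieved[["fA"]], fB = r$achieved[["fB"]],
               fC = r$achieved[["fC"]], fD = r$achieved[["fD"]],
               MC = r$achieved[["MC"]], EBV = r$achieved[["EBV"]],
               selected = r$selected_fraction,
               sd_cs = r$sd_male_contributions,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  slack <- lapply(results, function(r) {
    b <- r$bounds
    if (!length(b)) return(character(0))
    flags <- character(0)
    for (key in names(b)) {
      crit <- sub("^(ub|lb)_", "", key)
      ach <- r$achieved[[crit]]
      margin <- if (startsWith(key, "ub")) b[[key]] - ach else
        ach - b[[key]]
      flags[crit] <- if (margin > slack_tol) "slack" else "active"
    }
    flags
  })
  structure(tab, slack = slack, bounds = bounds,
            class = c("nocs_table", "data.frame"))
}

#' @export
print.nocs_table <- function(x, digits = 3, ...) {
  out <- as.data.frame(x)
  slack <- attr(x, "slack")
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], round, digits = digits)
  # mark constrained criteria: * active at its bound, ' satisfied with slack
  for (i in seq_len(nrow(out))) {
    fl <- slack[[out$scenario[i]]]
    for (crit in names(fl)) {
      if (crit %in% names(out)) {
        out[i, crit] <- paste0(format(out[i, crit]),
                               if (fl[crit] == "active") "*" else "'")
      }
    }
  }
  print.data.frame(out, row.names = FALSE)
  cat("(* constraint active at its bound, ' satisfied with slack)\n")
  invisible(x)
}

#' Write and read scenario tables at full precision
#'
#' The TSV channel round-trips the numeric values exactly (17 significant
#' digits); display rounding never feeds back into computation.
#'
#' @param tab a [summarize_scenarios()] table.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_scenario_table <- function(tab, path) {
  out <- as.data.frame(tab)
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(v) {
    vapply(v, function(x) {
      if (is.na(x)) "NA" else sprintf("%.17g", x)
    }, character(1))
  })
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_scenario_table
#' @param path path to a table written by [write_scenario_table()].
#' @export
read_scenario_table <- function(path) {
  out <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  for (col in setdiff(names(out), c("scenario", "status"))) {
    out[[col]] <- as.numeric(out[[col]])
  }
  out
}

#' Render a scenario table as a Markdown table
#'
#' @param tab a [summarize_scenarios()] table.
#' @param digits displayed decimals.
#' @return character vector of Markdown lines.
#' @export
format_markdown <- function(tab, digits = 3) {
  out <- as.data.frame(tab)
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(v) sprintf("%.*f", digits, v))
  cols <- names(out)
  c(paste0("| ", paste(cols, collapse = " | "), " |"),
    paste0("|", paste(rep("---", length(cols)), collapse = "|"), "|"),
    vapply(seq_len(nrow(out)), function(i) {
      paste0("| ", paste(unlist(out[i, ]), collapse = " | "), " |")
    }, character(1)))
}
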