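# Packaged scenario fixtures. Each pair of scenarios shares a rate set and
# differs only in the delay (0.01 vs 0.05); together the four pairs cover
# the model's qualitative regimes: persistent oscillation (no stability
# switch), a delay-induced stability switch, immune escape (unbounded tumor
# growth), and spontaneous tumor regression to the tumor-free equilibrium.
.ti_scenarios <- list(
  fig9  = list(a = c(0.3, 0.6, 4.0, 10.0), delta = 0.01, t_end = 400,
               note = paste("a2 > a1 and (a2-a1)a4 < a3 < a2a4: E1 and E2 both",
                            "exist and are unstable; sustained oscillation",
                            "around E2 at either delay (no stability switch)")),
  fig10 = list(a = c(0.3, 0.6, 4.0, 10.0), delta = 0.05, t_end = 400,
               note = "delay companion of fig9; still oscillatory"),
  fig11 = list(a = c(0.4, 0.6, 3.5, 7.0), delta = 0.01, t_end = 600,
               note = paste("a2 > a1 and (a2-a1)a4 < a3 < a2a4: E1 unstable,",
                            "E2 stable without delay; below the critical",
                            "delay, trajectories settle on E2")),
  fig12 = list(a = c(0.4, 0.6, 3.5, 7.0), delta = 0.05, t_end = 1000,
               note = paste("delay companion of fig11; above the critical",
                            "delay the equilibrium sheds a stable limit",
                            "cycle (delay-induced stability switch)")),
  fig13 = list(a = c(0.3, 0.6, 1.0, 5.0), delta = 0.01, t_end = 60,
               note = paste("a2 > a1 and 0 < a3 < (a2-a1)a4: only E1 exists",
                            "and is unstable; tumor burden grows without",
                            "bound (immune escape). Some running-text",
                            "accounts quote the fig11 rates for this case,",
                            "but those fail 0 < a3 < (a2-a1)a4; the caption",
                            "values used here satisfy it")),
  fig14 = list(a = c(0.3, 0.6, 1.0, 5.0), delta = 0.05, t_end = 60,
               note = "delay companion of fig13; still immune escape"),
  fig15 = list(a = c(0.3, 0.6, 0.5, 0.7), delta = 0.01, t_end = 300,
               note = paste("a3 > a2a4: only the tumor-free equilibrium E1",
                            "exists and it is asymptotically stable",
                            "(spontaneous tumor regression)")),
  fig16 = list(a = c(0.3, 0.6, 0.5, 0.7), delta = 0.05, t_end = 300,
               note = "delay companion of fig15; still tumor regression"))

#' Packaged simulation scenarios
#'
#' Eight named scenarios (`fig9` ... `fig16`) covering the model's four
#' qualitative regimes, in delay pairs (0.01 and 0.05). Histories are the
#' package default ([dde_solve()]): the relevant equilibrium perturbed by
#' +0.01 per component, held constant — the regime classifications are
#' insensitive to this choice, exact trajectories are not.
#'
#' @param name scenario name; see `scenario_names()`.
#' @return `load_scenario()` returns a list with `name`, `params`
#'   ([ti_params()]), `history`, `t_end`, and a provenance `note`;
#'   `scenario_names()` returns the available names.
#' @examples
#' load_scenario("fig11")$params
#' @export
load_scenario <- function(name) {
  if (!name %in% names(.ti_scenarios))
    stop("unknown scenario '", name, "'; available: ",
         paste(names(.ti_scenarios), collapse = ", "), call. = FALSE)
  sc <- .ti_scenarios[[name]]
  p <- ti_params(sc$a[1], sc$a[2], sc$a[3], sc$a[4], delta = sc$delta)
  list(name = name, params = p, history = default_history(p),
       t_end = sc$t_end, note = sc$note)
}

#' @rdname load_scenario
#' @export
scenario_names <- function() names(.ti_scenarios)

#' Write an analysis report to JSON or CSV
#'
#' JSON output has deterministic (sorted) key order, numbers at 12
#' significant digits, and complex values expanded to `re`/`im` pairs. CSV
#' output requires a data frame (or coercible) and expands complex columns
#' the same way; time-series frames keep the header `t,x,y,z`.
#'
#' @param results a list (JSON) or data frame (CSV).
#' @param path output file path.
#' @param format `"json"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, format = c("json", "csv")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(prep_json(results), path, auto_unbox = TRUE,
                         digits = NA, null = "null")
  } else {
    df <- as.data.frame(results)
    is_c <- vapply(df, is.complex, TRUE)
    if (any(is_c)) {
      for (nm in names(df)[is_c]) {
        df[[paste0(nm, "_re")]] <- Re(df[[nm]])
        df[[paste0(nm, "_im")]] <- Im(df[[nm]])
        df[[nm]] <- NULL
      }
    }
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

prep_json <- function(x) {
  if (is.list(x) && !is.data.frame(x)) {
    x <- lapply(x, prep_json)
    if (!is.null(names(x)) && all(nzchar(names(x))))
      x <- x[order(names(x))]
    return(x)
  }
  if (is.complex(x)) return(list(re = signif(Re(x), 12), im = signif(Im(x), 12)))
  if (is.numeric(x)) return(signif(x, 12))
  x
}

#' @rdname write_report
#' @export
read_report <- function(path, format = c("json", "csv")) {
  format <- match.arg(format)
  if (format == "json") jsonlite::fromJSON(path, simplifyVector = TRUE)
  else utils::read.csv(path)
}
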