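#' Protein ratio panels
#'
#' A protein panel is an ordered list of numerator/denominator protein pairs;
#' each pair becomes one log-ratio feature for the classifiers. Three panels are
#' packaged. The diagnostic panel (MS vs non-MS) holds 20 ratios over the 21
#' CSF proteins measurable on the 1.3k aptamer platform after loss of the IgG
#' heavy-chain reagent; the staging panel (RRMS vs progressive MS) holds 21
#' ratios over 24 proteins. For both, the protein lists follow the published
#' classifiers, while the pairings are a documented package default (the
#' historical pairings are not public) and can be replaced by any user panel.
#' The severity panel (57 ratios, 75 proteins) uses synthetic identifiers
#' (\code{SEVP001}..\code{SEVP075}) because the underlying protein list is not
#' public; it is shipped as \code{severity_panel_synthetic.csv}.
#'
#' Reagent identifiers are kept at reagent level; reagents targeting protein
#' complexes use an underscore (\code{TLR4_LY96}, \code{LTA_LTB}) so that the
#' slash stays reserved for ratio labels \code{"NUM/DEN"}.
#'
#' @param name one of \code{"diagnostic"}, \code{"progms"}, \code{"severity"}.
#' @return an object of class \code{protein_panel}: a list with elements
#'   \code{name}, \code{ratios} (data.frame with columns \code{numerator},
#'   \code{denominator}) and \code{proteins} (unique proteins referenced, in
#'   first-appearance order).
#' @seealso [load_panel()] for reading user-defined panels.
#' @export
#' @examples
#' p <- csf_panel("diagnostic")
#' nrow(p$ratios)      # 20
#' length(p$proteins)  # 21
csf_panel <- function(name = c("diagnostic", "progms", "severity")) {
  name <- match.arg(name)
  file <- switch(name,
    diagnostic = "diagnostic_panel.csv",
    progms     = "progms_panel.csv",
    severity   = "severity_panel_synthetic.csv"
  )
  path <- system.file("extdata", file, package = "csfmsval", mustWork = TRUE)
  load_panel(path)
}

#' Read a protein ratio panel from a CSV file
#'
#' The file must have columns \code{panel}, \code{numerator},
#' \code{denominator}. When the panel name matches one of the packaged panels,
#' the protein list is checked against the packaged list and a warning is
#' issued for unknown identifiers (user panels under other names are accepted
#' as-is).
#'
#' @param path path to a panel CSV.
#' @return a \code{protein_panel} object.
#' @export
load_panel <- function(path) {
  if (!file.exists(path)) stop_csf("panel file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("panel", "numerator", "denominator")
  if (!all(needed %in% names(df))) {
    stop_csf("panel file %s must have columns %s (found: %s)",
             path, paste(needed, collapse = ", "), paste(names(df), collapse = ", "))
  }
  bad <- which(is.na(df$numerator) | is.na(df$denominator) |
                 df$numerator == "" | df$denominator == "")
  if (length(bad)) {
    stop_csf("malformed panel row(s) at line(s) %s of %s (empty protein field)",
             paste(bad + 1L, collapse = ", "), path)
  }
  same <- which(df$numerator == df$denominator)
  if (length(same)) {
    stop_csf("ratio with identical numerator and denominator at line(s) %s of %s",
             paste(same + 1L, collapse = ", "), path)
  }
  name <- df$panel[1]
  if (!all(df$panel == name)) {
    stop_csf("panel file %s mixes panel names: %s",
             path, paste(unique(df$panel), collapse = ", "))
  }
  proteins <- unique(c(rbind(df$numerator, df$denominator)))
  panel <- structure(
    list(name = name,
         ratios = data.frame(numerator = df$numerator,
                             denominator = df$denominator,
                             stringsAsFactors = FALSE),
         proteins = proteins),
    class = "protein_panel"
  )
  known <- packaged_protein_lists()[[name]]
  if (!is.null(known)) {
    unknown <- setdiff(proteins, known)
    if (length(unknown)) {
      warn_csf("panel '%s': protein(s) not in the packaged %s list: %s",
               name, name, paste(unknown, collapse = ", "))
    }
  }
  panel
}

# Protein lists transcribed from the published classifier descriptions
# (diagnostic, staging) plus the synthetic severity identifiers.
packaged_protein_lists <- function() {
  list(
    diagnostic = c("TNFRSF17", "CD48", "PRTN3", "PLA2G7", "PDCD1LG2", "CCL7",
                   "SLAMF6", "TLR4_LY96", "CSF3", "CDKN1B", "TNFRSF6B", "TNC",
                   "CRK", "PGK1", "MAPK14", "FLT4", "F9", "CXCL13", "TNFRSF4",
                   "DCTPP1", "MMP7"),
    progms = c("EDA2R", "SELL", "CFD", "SERPING1", "ICOSLG", "LTA_LTB", "IL22",
               "INHBA", "GP6", "EDAR", "PRTN3", "LILRB2", "STX1A", "JAM3",
               "EPHA5", "GZMA", "NTRK3", "IL10", "CLEC1B", "TYRO3", "BOC",
               "ETHE1", "UNC5C", "RGMA"),
    severity = sprintf("SEVP%03d", 1:75)
  )
}

#' @export
print.protein_panel <- function(x, ...) {
  cat(sprintf("Protein panel '%s': %d ratios over %d unique proteins\n",
              x$name, nrow(x$ratios), length(x$proteins)))
  lab <- ratio_labels(x)
  show <- utils::head(lab, 5)
  cat("  ", paste(show, collapse = ", "),
      if (length(lab) > 5) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Ratio column labels ("NUM/DEN") of a panel, in panel order
#' @param panel a \code{protein_panel}.
#' @return character vector of ratio labels.
#' @export
ratio_labels <- function(panel) {
  paste(panel$ratios$numerator, panel$ratios$denominator, sep = "/")
}
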