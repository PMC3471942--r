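#' Collapse 8-state secondary structure to 3 states
#'
#' Standard mapping: `H`, `G`, `I` (helices) to `H`; `E`, `B` (strands/
#' bridges) to `E`; turns, bends and unassigned (`T`, `S`, `" "`) to `C`.
#' Whether isolated beta-bridges (`B`) group with strand or coil differs
#' between published pipelines, so the mapping is replaceable.
#'
#' @param ss8 Character vector of DSSP 8-state codes.
#' @param mapping Named character vector giving the 3-state class of each
#'   8-state code.
#' @return Character vector over `{"H","E","C"}`.
#' @export
ss8_to_ss3 <- function(ss8, mapping = SS8_TO_SS3_DEFAULT) {
  bad <- setdiff(unique(ss8), names(mapping))
  if (length(bad) > 0) {
    stop(sprintf("unknown secondary-structure code(s): '%s'",
                 paste(bad, collapse = "', '")), call. = FALSE)
  }
  unname(mapping[ss8])
}

#' @rdname ss8_to_ss3
#' @export
SS8_TO_SS3_DEFAULT <- c(H = "H", G = "H", I = "H",
                        E = "E", B = "E",
                        T = "C", S = "C", " " = "C", "-" = "C", C = "C")

#' Relative solvent accessibility
#'
#' Divides an absolute accessible surface area by the residue's maximum
#' reference area. The default scale is `AA_MAX_ASA`; any named per-residue
#' scale can be substituted. Values slightly above 1 can occur for extended
#' conformations and are kept.
#'
#' @param asa Accessible surface area, Angstrom^2, `>= 0`.
#' @param residue One-letter residue code (vectorised with `asa`).
#' @param scale Named numeric vector of per-residue maximum ASA.
#' @return Numeric vector of relative solvent accessibility.
#' @export
relative_sa <- function(asa, residue, scale = AA_MAX_ASA) {
  if (any(asa < 0)) stop("asa must be >= 0", call. = FALSE)
  bad <- setdiff(unique(residue), names(scale))
  if (length(bad) > 0) {
    stop(sprintf("no maximum-ASA value for residue(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  asa / unname(scale[residue])
}

#' Exposure state from relative solvent accessibility
#'
#' Binary exposure uses the 25% threshold: a residue is exposed when its
#' relative solvent accessibility is at least 0.25. The three-state version,
#' used to condition fragment potentials, adds an intermediate band
#' `[0.25, 0.50)`. A value exactly at a threshold goes to the higher-exposure
#' class.
#'
#' @param rsa Numeric vector of relative solvent accessibility, `>= 0`.
#' @param thresholds Length-2 numeric: the buried/intermediate and
#'   intermediate/exposed cut points.
#' @return Tibble with columns `exposure2` (`"buried"`/`"exposed"`) and
#'   `exposure3` (`"buried"`/`"intermediate"`/`"exposed"`).
#' @export
exposure_states <- function(rsa, thresholds = c(0.25, 0.50)) {
  if (any(rsa < 0)) stop("rsa must be >= 0", call. = FALSE)
  stopifnot(length(thresholds) == 2, thresholds[1] < thresholds[2])
  exposure2 <- ifelse(rsa >= thresholds[1], "exposed", "buried")
  exposure3 <- ifelse(rsa >= thresholds[2], "exposed",
                      ifelse(rsa >= thresholds[1], "intermediate", "buried"))
  tibble::tibble(exposure2 = exposure2, exposure3 = exposure3)
}

# per-residue states (ss3 + exposure classes) for one protein row;
# errors if a required layer is missing
residue_states <- function(proteins, protein_id, thresholds = c(0.25, 0.50)) {
  row <- protein_row(proteins, protein_id)
  ss3 <- row$ss3[[1]]
  rsa <- row$rsa[[1]]
  if (is.null(ss3) || is.null(rsa)) {
    stop(sprintf("protein '%s' lacks ss3/rsa annotation", protein_id),
         call. = FALSE)
  }
  exp <- exposure_states(rsa, thresholds)
  tibble::tibble(pos = seq_along(ss3), ss3 = ss3,
                 exposure2 = exp$exposure2, exposure3 = exp$exposure3)
}
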