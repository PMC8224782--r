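# Tissue:plasma partitioning (Rodgers & Rowland), blood:plasma ratio and
# protein-binding scaling.

#' Tissue composition table
#'
#' Returns the packaged tissue-composition table used by the
#' Rodgers-Rowland partition equations: fractional extracellular and
#' intracellular water, neutral lipids, neutral phospholipids, acidic
#' phospholipid content (mg/g), tissue-to-plasma albumin ratio and
#' intracellular pH. Each row carries a provenance note. Special rows
#' `plasma` and `blood_cells` hold the plasma and erythrocyte compositions.
#'
#' @return data.frame with one row per tissue
#' @export
tissue_composition <- function() {
  read.csv(system.file("extdata", "tissue_composition.csv",
                       package = "cabopbpk", mustWork = TRUE),
           stringsAsFactors = FALSE)
}

#' Tissue:plasma partition coefficients (Rodgers & Rowland)
#'
#' Computes steady-state tissue:plasma partition coefficients for a monoprotic
#' base from tissue composition. Two published equation branches are used:
#'
#' * `pKa_base < 7` (weak/neutral base; the cabozantinib case, pKa 6.32):
#'   partitioning into tissue water, neutral lipids and neutral phospholipids
#'   plus residual binding to tissue proteins (albumin-type), with the protein
#'   association constant back-calculated from plasma `fu`.
#' * `pKa_base >= 7` (moderate-to-strong base): the acidic-phospholipid
#'   association branch, with the association constant back-calculated from
#'   the red-blood-cell partition coefficient `kp_rbc` (must be > 0 in this
#'   branch).
#'
#' Returned values are tissue:plasma coefficients `Kp = Kpu * fu`.
#'
#' Following the published method, the neutral-lipid partition coefficient
#' for adipose tissue uses the vegetable-oil:water correlation
#' `log D_vo = 1.115 * logP - 1.35` instead of the octanol:water value used
#' for all other tissues; octanol overestimates triglyceride partitioning of
#' lipophilic compounds by more than an order of magnitude.
#'
#' @param drug a [drug_parameters()] object
#' @param comp tissue-composition data.frame as from [tissue_composition()];
#'   must contain a `plasma` row (and a `blood_cells` row for the
#'   strong-base branch)
#' @param tissues character vector of tissues to compute; default all
#'   non-special rows of `comp`
#' @param fu optional fraction unbound overriding `drug$fu_plasma` (used by
#'   the impairment scenario layer)
#' @return object of class `partition_set`: list with `kp` (named numeric),
#'   `blood_plasma_ratio`, `fu`, `branch`
#' @export
kp_rodgers_rowland <- function(drug, comp = tissue_composition(),
                               tissues = NULL, fu = NULL) {
  stopifnot(inherits(drug, "drug_parameters"))
  fu <- fu %||% drug$fu_plasma
  check_range(fu, "fu", 0, 1, open_lower = TRUE)
  pka <- drug$pKa_base
  P <- 10^drug$logP
  pl <- comp[comp$tissue == "plasma", ]
  if (nrow(pl) != 1L) stop("composition table lacks a `plasma` row", call. = FALSE)
  ph_p <- pl$ph_iw
  if (is.null(tissues)) {
    tissues <- setdiff(comp$tissue, c("plasma", "blood_cells"))
  }
  missing_rows <- setdiff(tissues, comp$tissue)
  if (length(missing_rows)) {
    stop("missing composition row for tissue(s): ",
         paste(missing_rows, collapse = ", "), call. = FALSE)
  }
  Y <- 1 + 10^(pka - ph_p)                    # plasma ionisation
  # plasma lipid partitioning of the neutral species
  lip_p <- (P * pl$f_nl + (0.3 * P + 0.7) * pl$f_np) / Y

  branch <- if (pka < 7) "weak_base" else "strong_base"
  kaap <- NULL
  if (branch == "strong_base") {
    bc <- comp[comp$tissue == "blood_cells", ]
    if (nrow(bc) != 1L) {
      stop("strong-base branch needs a `blood_cells` composition row",
           call. = FALSE)
    }
    if (drug$kp_rbc <= 0) {
      stop("strong-base branch requires kp_rbc > 0 to calibrate the acidic-",
           "phospholipid association constant", call. = FALSE)
    }
    kpu_bc <- drug$kp_rbc / fu
    X_bc <- 1 + 10^(pka - bc$ph_iw)
    resid <- kpu_bc - X_bc / Y * bc$f_iw -
      (P * bc$f_nl + (0.3 * P + 0.7) * bc$f_np) / Y
    kaap <- max(0, resid) * Y / (bc$ap_mg_g * 10^(pka - bc$ph_iw))
  }

  P_vo <- 10^(1.115 * drug$logP - 1.35)       # vegetable oil : water
  kp <- vapply(tissues, function(tn) {
    row <- comp[comp$tissue == tn, ]
    X <- 1 + 10^(pka - row$ph_iw)             # intracellular ionisation
    water <- row$f_ew + row$f_iw * X / Y
    P_nl <- if (tn == "adipose") P_vo else P
    lipid <- (P_nl * row$f_nl + (0.3 * P + 0.7) * row$f_np) / Y
    kpu <- if (branch == "weak_base") {
      prot <- row$alb_ratio * max(0, 1 / fu - 1 - lip_p)
      water + lipid + prot
    } else {
      water + lipid + kaap * row$ap_mg_g * 10^(pka - row$ph_iw) / Y
    }
    kpu * fu
  }, numeric(1))

  structure(
    list(kp = kp,
         blood_plasma_ratio = blood_plasma_ratio(fu, 0.45, drug$kp_rbc),
         fu = fu, branch = branch),
    class = "partition_set"
  )
}

#' @export
print.partition_set <- function(x, ...) {
  cat(sprintf("<partition_set> %s branch, fu %.4g, B:P %.3g\n",
              x$branch, x$fu, x$blood_plasma_ratio))
  print(round(x$kp, 3))
  invisible(x)
}

#' Blood:plasma concentration ratio
#'
#' `B:P = (1 - hct) + hct * kp_rbc * fu`, where `kp_rbc` is the red blood
#' cell to plasma-water partition coefficient. With `kp_rbc = 0` the drug is
#' confined to plasma and `B:P = 1 - hct`.
#'
#' @param fu fraction unbound in plasma
#' @param hct haematocrit, in (0, 1); `hct = 0` is permitted and returns 1
#' @param kp_rbc red-blood-cell partition coefficient, >= 0
#' @return dimensionless ratio
#' @export
blood_plasma_ratio <- function(fu, hct, kp_rbc = 0) {
  check_range(fu, "fu", 0, 1, open_lower = TRUE)
  check_range(hct, "hct", 0, 1, open_upper = TRUE)
  check_range(kp_rbc, "kp_rbc", 0)
  (1 - hct) + hct * kp_rbc * fu
}

#' Scale the unbound plasma fraction with binding-protein concentration
#'
#' Rescales `fu` when the binding-protein concentration is multiplied by
#' `protein_scale` at constant affinity:
#' `fu' = 1 / (1 + protein_scale * (1 - fu) / fu)`.
#' `protein_scale = 1` is the identity; `protein_scale = 0` (no binding
#' protein) gives `fu' = 1`. Used by the hepatic-impairment scenario layer,
#' where the plasma protein scale factor strongly influences exposure and
#' peak concentration.
#'
#' @param fu baseline fraction unbound, (0, 1]
#' @param protein_scale binding-protein concentration scale, >= 0
#' @return scaled fraction unbound in (0, 1]
#' @export
scaled_fu <- function(fu, protein_scale) {
  check_range(fu, "fu", 0, 1, open_lower = TRUE)
  check_range(protein_scale, "protein_scale", 0)
  1 / (1 + protein_scale * (1 - fu) / fu)
}
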