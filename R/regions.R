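#' AAL-style parcellation labels
#'
#' Returns the first `n` region labels of the standard 90-region automated
#' anatomical labelling (AAL) cortical/subcortical parcellation, in the
#' conventional left/right interleaved order. Simulated cohorts use these as
#' their region names so that exported edge lists and hub tables read like
#' source-space MEG output.
#'
#' @param n number of regions (1-90).
#' @return character vector of length `n`.
#' @export
aal_labels <- function(n = 90) {
  base <- c(
    "Precentral", "Frontal_Sup", "Frontal_Sup_Orb", "Frontal_Mid",
    "Frontal_Mid_Orb", "Frontal_Inf_Oper", "Frontal_Inf_Tri",
    "Frontal_Inf_Orb", "Rolandic_Oper", "Supp_Motor_Area", "Olfactory",
    "Frontal_Sup_Medial", "Frontal_Med_Orb", "Rectus", "Insula",
    "Cingulum_Ant", "Cingulum_Mid", "Cingulum_Post", "Hippocampus",
    "ParaHippocampal", "Amygdala", "Calcarine", "Cuneus", "Lingual",
    "Occipital_Sup", "Occipital_Mid", "Occipital_Inf", "Fusiform",
    "Postcentral", "Parietal_Sup", "Parietal_Inf", "SupraMarginal",
    "Angular", "Precuneus", "Paracentral_Lobule", "Caudate", "Putamen",
    "Pallidum", "Thalamus", "Heschl", "Temporal_Sup", "Temporal_Pole_Sup",
    "Temporal_Mid", "Temporal_Pole_Mid", "Temporal_Inf")
  full <- as.vector(rbind(paste0(base, "_L"), paste0(base, "_R")))
  if (n < 1 || n > length(full))
    stop(sprintf("n must be between 1 and %d", length(full)))
  full[seq_len(n)]
}
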