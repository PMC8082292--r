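# Shared fixtures: published confusion matrices, a catalogue of real
# pyradiomics-style feature names, and small toy-data builders.

# Catalogue of 41 real radiomics feature names following the
# <filter>_<class>_<name>_<sequence>_<region> convention.
radiomics_name_catalogue <- c(
  "wavelet.HL_firstorder_Mean_cT1_L2",
  "wavelet.HH_gldm_DependenceVariance_T2_L2",
  "wavelet.HL_glszm_SmallAreaLowGrayLevelEmphasis_FLAIR_L3",
  "log.sigma.2.mm.3D_firstorder_90Percentile_cT1_L2",
  "original_shape_MinorAxisLength_T1_L2",
  "wavelet2.LL_firstorder_Mean_T2_L3",
  "wavelet2.HL_glszm_LargeAreaHighGrayLevelEmphasis_T1_L2",
  "wavelet.LH_gldm_LargeDependenceHighGrayLevelEmphasis_T1_L2",
  "wavelet2.HH_glcm_Idm_T2_L2",
  "original_firstorder_Mean_T2_L3",
  "wavelet.HL_firstorder_10Percentile_T2_L2",
  "wavelet2.LH_gldm_LowGrayLevelEmphasis_FLAIR_L3",
  "log.sigma.3.mm.3D_firstorder_MeanAbsoluteDeviation_cT1_L3",
  "wavelet.HL_firstorder_RootMeanSquared_cT1_L2",
  "log.sigma.3.mm.3D_ngtdm_Strength_T2_L2",
  "wavelet2.HH_glrlm_GrayLevelNonUniformity_T2_L2",
  "wavelet2.HL_gldm_LargeDependenceHighGrayLevelEmphasis_T1_L2",
  "wavelet.HL_glszm_GrayLevelNonUniformity_T2_L2",
  "log.sigma.1.015625.mm.3D_firstorder_Mean_T2_L1",
  "wavelet2.HH_gldm_LargeDependenceLowGrayLevelEmphasis_T1_L2",
  "wavelet2.HL_gldm_LargeDependenceLowGrayLevelEmphasis_T1_L2",
  "wavelet.HH_glcm_SumEntropy_T2_L2",
  "wavelet2.LL_glcm_MCC_T2_L2",
  "wavelet.LH_glcm_Correlation_cT1_L3",
  "wavelet2.HL_glszm_ZoneEntropy_T1_L2",
  "wavelet.HL_glszm_ZoneEntropy_T1_L2",
  "wavelet2.HH_glcm_InverseVariance_T2_L2",
  "wavelet2.HH_glszm_LargeAreaLowGrayLevelEmphasis_T1_L1",
  "wavelet2.LL_glcm_MaximumProbability_FLAIR_L3",
  "wavelet2.LL_glcm_ClusterShade_cT1_L3",
  "wavelet.HL_gldm_DependenceVariance_FLAIR_L3",
  "wavelet.LH_glszm_SizeZoneNonUniformity_FLAIR_L1",
  "wavelet.HL_glszm_LargeAreaHighGrayLevelEmphasis_T1_L2",
  "wavelet.HL_glcm_Correlation_FLAIR_L1",
  "wavelet2.HH_firstorder_10Percentile_T2_L2",
  "log.sigma.1.015625.mm.3D_ngtdm_Contrast_T2_L2",
  "log.sigma.3.mm.3D_gldm_LargeDependenceLowGrayLevelEmphasis_FLAIR_L3",
  "wavelet2.HL_glcm_ClusterShade_cT1_L3",
  "log.sigma.1.015625.mm.3D_glrlm_ShortRunLowGrayLevelEmphasis_T1_L3",
  "log.sigma.3.mm.3D_glrlm_GrayLevelVariance_cT1_L3",
  "original_shape_LeastAxisLength_T2_L2")

# Published held-out confusion matrices (rows = prediction, columns =
# reference; order mutant, wild-type), with the published test-set point
# metrics under the wild-type-positive convention. Layout per entry:
# cm = c(pred-mut/ref-mut, pred-mut/ref-WT, pred-WT/ref-mut, pred-WT/ref-WT).
published_confusions <- list(
  center1_A1 = list(cm = c(3, 1, 1, 2), sens = 0.67, spec = 0.75, acc = 0.71, mcc = 0.42),
  center1_A2 = list(cm = c(3, 1, 1, 2), sens = 0.67, spec = 0.75, acc = 0.71, mcc = 0.42),
  center1_B  = list(cm = c(3, 1, 1, 2), sens = 0.67, spec = 0.75, acc = 0.71, mcc = 0.42),
  center2_A1 = list(cm = c(9, 1, 2, 0), sens = 0.00, spec = 0.82, acc = 0.75, mcc = -0.13),
  center2_A2 = list(cm = c(8, 1, 3, 0), sens = 0.00, spec = 0.73, acc = 0.67, mcc = -0.17),
  center2_B  = list(cm = c(10, 1, 1, 0), sens = 0.00, spec = 0.91, acc = 0.83, mcc = -0.09),
  center3_A1 = list(cm = c(21, 1, 8, 6), sens = 0.86, spec = 0.72, acc = 0.75, mcc = 0.47),
  center3_A2 = list(cm = c(24, 3, 5, 4), sens = 0.57, spec = 0.83, acc = 0.78, mcc = 0.36),
  center3_B  = list(cm = c(23, 1, 6, 6), sens = 0.86, spec = 0.79, acc = 0.81, mcc = 0.55),
  center4_A1 = list(cm = c(5, 7, 2, 8), sens = 0.53, spec = 0.71, acc = 0.59, mcc = 0.23),
  center4_A2 = list(cm = c(6, 13, 1, 2), sens = 0.13, spec = 0.86, acc = 0.36, mcc = -0.01),
  center4_B  = list(cm = c(6, 15, 1, 0), sens = 0.00, spec = 0.86, acc = 0.27, mcc = -0.32),
  mix_A1     = list(cm = c(11, 4, 4, 3), sens = 0.43, spec = 0.73, acc = 0.64, mcc = 0.16),
  mix_A2     = list(cm = c(13, 1, 2, 6), sens = 0.86, spec = 0.87, acc = 0.86, mcc = 0.70),
  mix_B      = list(cm = c(13, 4, 2, 3), sens = 0.43, spec = 0.87, acc = 0.73, mcc = 0.33))

# Wild-type-positive confusion matrix from the published layout.
wt_confusion <- function(cm4) {
  confusion_from_counts(tp = cm4[4], fp = cm4[3], fn = cm4[2], tn = cm4[1],
                        positive = "wildtype", negative = "mutant")
}

# Toy single-mechanism cohort split arbitrarily into environments.
toy_cohort <- function(n = 100, beta = c(1, -0.7), n_env = 2, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * length(beta)), n, length(beta))
  y <- rbinom(n, 1, plogis(drop(X %*% beta)))
  ids <- paste0("s", seq_len(n))
  tab <- feature_table(X, ids, paste0("original_firstorder_Toy", seq_along(beta),
                                      "_T1_L1"))
  md <- cohort_metadata(ids, rep_len(paste0("e", seq_len(n_env)), n),
                        ifelse(y == 1, "wildtype", "mutant"),
                        positive_class = "wildtype")
  list(table = tab, metadata = md, y = y)
}

# Two well-separated Gaussian blobs (linearly separable).
separable_cohort <- function(n = 60, seed = 1) {
  set.seed(seed)
  y <- rep(0:1, each = n / 2)
  X <- cbind(rnorm(n, mean = 8 * y), rnorm(n))
  ids <- paste0("s", seq_len(n))
  tab <- feature_table(X, ids, c("original_firstorder_Sep_T1_L1",
                                 "original_firstorder_Flat_T1_L1"))
  md <- cohort_metadata(ids, rep_len(c("e1", "e2"), n),
                        ifelse(y == 1, "wildtype", "mutant"),
                        positive_class = "wildtype")
  list(table = tab, metadata = md, y = y)
}
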