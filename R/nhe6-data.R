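#' Published group summaries for the Nhe6-null mouse ageing study
#'
#' Group summary statistics (mean, SEM, n) for brain-region measurements in
#' wild-type (`WT`) and Nhe6-null (`MUT`) mice across postnatal life, keyed
#' in from the published summary tables of the mouse model of Christianson
#' syndrome so that every downstream analysis (trajectory fits, atrophy
#' percentages, summary-statistic tests) can be recomputed with no external
#' data. Gross areas are in cm^2, histology areas in mm^2, cortical
#' thickness and spinal-cord width in mm, Purkinje-cell density in cells per
#' 100 um of layer, calbindin signal in percent coverage, microglia counts
#' as summed cell counts, and puncta sizes in um^2.
#'
#' Ages are in months with postnatal day 0 encoded as 0; pooled age groups
#' keep their label in `age_label` (the 23-26-month group is encoded as age
#' 23, the 11-13-month group as 12). `subregion` distinguishes cerebellar
#' vermis lobules and the two spinal-cord measurement levels. `cohort`
#' separates the exon-6 model (`exon6`, male), its female comparison
#' (`exon6_female`), and the exons-2/3 model (`exons2_3`).
#'
#' @return A tibble with columns `panel`, `cohort`, `measure_kind`,
#'   `region`, `subregion`, `age_label`, `age_months`, `genotype`, `mean`,
#'   `sem`, `n`.
#' @export
#' @examples
#' dplyr::filter(nhe6_group_summaries(),
#'   region == "cerebellum", measure_kind == "gross_area")
nhe6_group_summaries <- function() {
  row <- function(panel, cohort, kind, region, sub, lbl, age,
                  wm, ws, wn, mm, ms, mn) {
    tibble(
      panel = panel, cohort = cohort, measure_kind = kind, region = region,
      subregion = sub, age_label = lbl, age_months = age,
      genotype = c("WT", "MUT"),
      mean = c(wm, mm), sem = c(ws, ms), n = as.integer(c(wn, mn))
    )
  }
  g <- function(region, age, wm, ws, wn, mm, ms, mn) {
    row("gross_area_trajectory", "exon6", "gross_area", region,
      NA_character_, as.character(age), age, wm, ws, wn, mm, ms, mn)
  }
  dplyr::bind_rows(
    # --- gross brain areas across the lifespan (cm^2) ---
    g("whole_brain", 0, 0.376, 0.021, 9, 0.394, 0.011, 12),
    g("whole_brain", 1, 1.015, 0.012, 11, 1.030, 0.030, 7),
    g("whole_brain", 2, 1.257, 0.033, 8, 1.112, 0.042, 6),
    g("whole_brain", 6, 1.326, 0.011, 7, 1.243, 0.011, 6),
    g("whole_brain", 23, 1.105, 0.013, 4, 1.0068, 0.0073, 5),
    g("cortex", 0, 0.244, 0.013, 9, 0.2499, 0.0083, 12),
    g("cortex", 1, 0.7527, 0.0074, 11, 0.766, 0.020, 7),
    g("cortex", 2, 0.908, 0.027, 8, 0.808, 0.030, 6),
    g("cortex", 6, 0.949, 0.011, 7, 0.907, 0.012, 6),
    g("cortex", 23, 0.7723, 0.0089, 4, 0.7501, 0.0031, 5),
    g("cerebellum", 0, 0.0316, 0.0024, 9, 0.0323, 0.0016, 12),
    g("cerebellum", 1, 0.2188, 0.0050, 11, 0.2210, 0.0088, 7),
    g("cerebellum", 2, 0.2913, 0.0056, 8, 0.254, 0.011, 6),
    g("cerebellum", 6, 0.3006, 0.0037, 7, 0.2590, 0.0059, 6),
    g("cerebellum", 23, 0.2483, 0.0078, 4, 0.1760, 0.0057, 5),
    g("cerebellum_midbrain", 0, 0.153, 0.014, 9, 0.1441, 0.0029, 12),
    g("cerebellum_midbrain", 1, 0.2619, 0.0062, 11, 0.264, 0.010, 7),
    g("cerebellum_midbrain", 2, 0.3484, 0.0083, 8, 0.304, 0.016, 6),
    g("cerebellum_midbrain", 6, 0.3776, 0.0012, 7, 0.3365, 0.0078, 6),
    g("cerebellum_midbrain", 23, 0.3124, 0.0064, 4, 0.2368, 0.0068, 5),
    # --- histology at 22 months (Nissl sections) ---
    row("histology_aged", "exon6", "thickness", "cortex", NA, "22", 22,
      1.210, 0.029, 3, 1.090, 0.018, 3),
    row("histology_aged", "exon6", "tissue_area", "striatum", NA, "22", 22,
      4.689, 0.030, 3, 4.062, 0.045, 3),
    row("histology_aged", "exon6", "tissue_area", "hippocampus", NA, "22", 22,
      2.455, 0.047, 3, 2.074, 0.068, 3),
    row("histology_aged", "exon6", "tissue_area", "cerebellum", NA, "22", 22,
      7.128, 0.014, 2, 4.586, 0.089, 4),
    row("histology_aged", "exon6", "width", "spinal_cord", "region1", "22", 22,
      1.890, 0.073, 2, 1.491, 0.073, 2),
    row("histology_aged", "exon6", "width", "spinal_cord", "region2", "22", 22,
      1.987, 0.080, 2, 1.845, 0.033, 2),
    # --- histology at 2 months (trajectory comparison against 22 months) ---
    row("histology_young", "exon6", "thickness", "cortex", NA, "2", 2,
      1.154, 0.018, 3, 1.126, 0.029, 3),
    row("histology_young", "exon6", "tissue_area", "striatum", NA, "2", 2,
      4.060, 0.077, 3, 3.83, 0.12, 3),
    row("histology_young", "exon6", "tissue_area", "hippocampus", NA, "2", 2,
      2.199, 0.011, 3, 2.113, 0.062, 3),
    row("histology_young", "exon6", "tissue_area", "cerebellum", NA, "2", 2,
      6.53, 0.15, 3, 5.91, 0.16, 3),
    # --- Purkinje-cell density and calbindin coverage, vermis ---
    row("pc_vermis", "exon6", "pc_density", "cerebellum", "primary_fissure",
      "5", 5, 2.94, 0.13, 3, 1.99, 0.24, 3),
    row("pc_vermis", "exon6", "signal_fraction", "cerebellum",
      "primary_fissure", "5", 5, 32.9, 2.8, 4, 15.5, 1.7, 4),
    row("pc_vermis", "exon6", "pc_density", "cerebellum", "primary_fissure",
      "11-13", 12, 3.28, 0.28, 5, 0.77, 0.26, 4),
    row("pc_vermis", "exon6", "signal_fraction", "cerebellum",
      "primary_fissure", "11-13", 12, 30.7, 3.6, 6, 8.80, 0.92, 4),
    row("pc_lobules", "exon6", "pc_density", "cerebellum", "anterior_lobe",
      "5", 5, 3.27, 0.24, 3, 0.74, 0.44, 4),
    row("pc_lobules", "exon6", "pc_density", "cerebellum",
      "flocculonodular_lobe", "5", 5, 3.49, 0.36, 3, 2.42, 0.52, 3),
    row("pc_lobules", "exon6", "pc_density", "cerebellum", "anterior_lobe",
      "11-13", 12, 3.22, 0.30, 4, 0.21, 0.13, 3),
    row("pc_lobules", "exon6", "pc_density", "cerebellum",
      "flocculonodular_lobe", "11-13", 12, 3.31, 0.43, 4, 2.78, 0.51, 3),
    # --- exons-2/3 model, 6 months ---
    row("pc_exons2_3", "exons2_3", "pc_density", "cerebellum",
      "primary_fissure", "6", 6, 3.25, 0.07, 2, 1.02, 0.38, 3),
    row("pc_exons2_3", "exons2_3", "pc_density", "cerebellum",
      "anterior_lobe", "6", 6, 3.80, 0.12, 2, 0.84, 0.58, 3),
    row("pc_exons2_3", "exons2_3", "pc_density", "cerebellum",
      "flocculonodular_lobe", "6", 6, 3.51, 0.43, 2, 3.24, 0.54, 3),
    # --- female comparison, 5 months ---
    row("pc_female", "exon6_female", "pc_density", "cerebellum",
      "primary_fissure", "5", 5, 3.05, 0.35, 3, 0.83, 0.45, 4),
    row("pc_female", "exon6_female", "signal_fraction", "cerebellum",
      "primary_fissure", "5", 5, 32.1, 2.5, 3, 13.3, 1.4, 4),
    # --- microglia counts at 22 months (summed over tiles) ---
    row("microglia", "exon6", "cell_count", "cortex", NA, "22", 22,
      159, 15, 3, 219, 10, 4),
    row("microglia", "exon6", "cell_count", "striatum", NA, "22", 22,
      398.7, 5.6, 3, 568, 30, 4),
    row("microglia", "exon6", "cell_count", "hippocampus_CA", NA, "22", 22,
      74.0, 4.4, 3, 100.0, 3.4, 4),
    row("microglia", "exon6", "cell_count", "hippocampus_DG", NA, "22", 22,
      56.0, 6.7, 3, 67.3, 3.9, 4),
    # --- CD68 puncta sizes in Iba1-positive cells at 22 months (um^2) ---
    row("puncta", "exon6", "puncta_area", "cortex", NA, "22", 22,
      19.76, 0.49, 3, 28.0, 2.0, 3),
    row("puncta", "exon6", "puncta_area", "striatum", NA, "22", 22,
      20.5, 2.0, 3, 29.9, 4.0, 3),
    row("puncta", "exon6", "puncta_area", "hippocampus_DG", NA, "22", 22,
      7.2, 2.2, 3, 10.8, 2.5, 3)
  )
}

#' Published growth and degeneration coefficients
#'
#' The published per-phase modeling results for cortex and cerebellum in the
#' Nhe6-null mouse study: interval rates of change (cm^2/month), wild-type
#' baseline growth (`G`) and degeneration (`D`) coefficients, and the mutant
#' undergrowth-only and degeneration-only counterfactual coefficients
#' (month^-1). Kept as printed, so reproductions by [fit_baseline()] and
#' [fit_counterfactual()] can be compared cell by cell. Note the published
#' values were computed from unrounded group means, so a reproduction from
#' the rounded means of [nhe6_group_summaries()] matches large coefficients
#' closely but can differ visibly where coefficients are small or formed as
#' differences of near-equal numbers.
#'
#' @return A tibble with columns `region`, `t_start`, `t_end`, `wt_rate`,
#'   `wt_G`, `wt_D`, `mut_rate`, `ug_G`, `ug_D` (undergrowth-only), `dg_G`,
#'   `dg_D` (degeneration-only).
#' @export
nhe6_published_coefficients <- function() {
  tibble::tribble(
    ~region, ~t_start, ~t_end, ~wt_rate, ~wt_G, ~wt_D,
    ~mut_rate, ~ug_G, ~ug_D, ~dg_G, ~dg_D,
    "cortex", 0, 1, 0.5092, 0.6764, 0, 0.516, 0.6737, 0, 0.6764, 0.0027,
    "cortex", 1, 2, 0.156, 0.1712, 0, 0.0415, 0.0514, 0, 0.1712, 0.1198,
    "cortex", 2, 6, 0.0101, 0.0106, 0, 0.0248, 0.0274, 0, 0.0106, -0.0168,
    "cortex", 6, 23, -0.01037, 0, 0.0134, -0.00922, 0, 0.0123, 0, 0.0123,
    "cerebellum", 0, 1, 0.1873, 0.8558, 0, 0.1887, 0.8537, 0, 0.8558, 0.0021,
    "cerebellum", 1, 2, 0.07243, 0.2487, 0, 0.0332, 0.1305, 0, 0.2487, 0.1182,
    "cerebellum", 2, 6, 0.00233, 0.0078, 0, 0.0012, 0.0047, 0, 0.0078, 0.0031,
    "cerebellum", 6, 23, -0.00308, 0, 0.0124, -0.00488, 0, 0.0277, 0, 0.0277
  )
}
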