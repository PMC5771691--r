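# Shared fixtures, all built in code.

# A small well-formed measurement table.
make_records <- function() {
  tibble::tibble(
    subject_id = c("m1", "m2", "m3", "m4"),
    genotype = c("WT", "WT", "MUT", "MUT"),
    sex = "M",
    age_months = c(23, 23, 23, 23),
    region = "cerebellum",
    measure_kind = "gross_area",
    value = c(0.24, 0.26, 0.17, 0.18),
    units = "cm^2"
  )
}

write_records_tsv <- function(records, path = tempfile(fileext = ".tsv")) {
  readr::write_tsv(records, path, progress = FALSE)
  path
}

# Four values with mean 0.2483 and SEM 0.0078 (n = 4), by symmetric
# placement: sd = 0.0078 * 2 = 0.0156, offsets +/- sd * sqrt(3)/2.
cerebellum_aged_values <- function() {
  m <- 0.2483
  a <- 0.0156 * sqrt(3) / 2
  c(m - a, m - a, m + a, m + a)
}

# Pull one (mean, sem, n) cell out of the packaged published summaries.
nhe6_cell <- function(kind, region, age, genotype, subregion = NA,
                      cohort = "exon6") {
  d <- nhe6_group_summaries()
  d <- d[d$measure_kind == kind & d$region == region &
         d$age_months == age & d$genotype == genotype &
         d$cohort == cohort, ]
  if (!is.na(subregion)) d <- d[!is.na(d$subregion) & d$subregion == subregion, ]
  stopifnot(nrow(d) == 1)
  d[, c("mean", "sem", "n")]
}

# Gross-area anchors for one region x genotype, ordered by age.
nhe6_anchors <- function(region, genotype) {
  d <- nhe6_group_summaries()
  d <- d[d$measure_kind == "gross_area" & d$region == region &
         d$genotype == genotype, ]
  d <- d[order(d$age_months), ]
  tibble::tibble(t = d$age_months, area = d$mean)
}
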