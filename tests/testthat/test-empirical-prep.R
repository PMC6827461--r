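test_that("the focal site set is the ten copy-number control positions", {
  s <- focal_site_set()
  expect_length(s, 10L)
  expect_true(3118 %in% s)
  expect_false(3117 %in% s)
  expect_false(3036 %in% s)
  expect_equal(min(s), 3027L)
  expect_equal(max(s), 3118L)
})

make_records <- function(position, family_count, dcs_depth,
                         ref = "C", alt = "T", hours = 12, rep = "R6") {
  data.frame(replicate = rep, time_point_hours = hours, position = position,
             ref = ref, alt = alt, family_count = family_count,
             dcs_depth = dcs_depth)
}

test_that("the empirical mutant frequency sums focal SNV frequencies only", {
  rec <- rbind(make_records(3027, 20, 1e4),   # 0.002
               make_records(3118, 10, 1e4),   # 0.001
               make_records(1500, 1, 1e4))    # flickering, excluded
  expect_equal(empirical_mutant_frequency(rec), 0.003)

  # no focal records at all
  expect_equal(empirical_mutant_frequency(make_records(1500, 1, 1e4)), 0)

  # monomorphic initial sample: single-family non-focal calls only
  mono <- rbind(make_records(210, 1, 9000), make_records(4100, 1, 9000))
  expect_equal(empirical_mutant_frequency(mono), 0)

  # multiple alternate alleles at one focal site are summed
  two_alt <- rbind(make_records(3030, 5, 1e4, alt = "T"),
                   make_records(3030, 3, 1e4, alt = "A"))
  expect_equal(empirical_mutant_frequency(two_alt), 8e-4)

  # indels at focal sites are excluded from the sum
  with_indel <- rbind(make_records(3031, 10, 1e4),
                      make_records(3032, 50, 1e4, ref = "C", alt = "CT"))
  expect_equal(empirical_mutant_frequency(with_indel), 1e-3)

  expect_error(empirical_mutant_frequency(make_records(3027, 0, 0)),
               "dcs_depth")
  expect_warning(
    x <- empirical_mutant_frequency(rbind(make_records(3027, 100, 100),
                                          make_records(3028, 100, 100))),
    "clamping")
  expect_equal(x, 1)
})

test_that("frequency sums are additive over disjoint focal subsets", {
  a <- make_records(3027, 12, 2e4)
  b <- rbind(make_records(3033, 7, 2e4), make_records(3118, 4, 2e4))
  expect_equal(empirical_mutant_frequency(rbind(a, b)),
               empirical_mutant_frequency(a) + empirical_mutant_frequency(b))
})

test_that("variant tables round-trip through TSV and the VCF-like dialect maps fields", {
  tab <- rbind(make_records(3027, 20, 1e4, hours = 12),
               make_records(3118, 5, 1e4, hours = 24),
               make_records(900, 1, 1e4, hours = 24))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_variant_table(tab, path)
  back <- read_variant_table(path)
  expect_equal(back, tab, ignore_attr = TRUE)

  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCF-like duplex dialect",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "pBR322\t3027\t.\tC\tT\t.\tPASS\tDP=10000;AC=20;TP=12;RUN=R6",
    "pBR322\t3118\t.\tC\tT\t.\tPASS\tAC=5;DP=10000;TP=24;RUN=R6"), vcf)
  imported <- read_variant_vcf(vcf)
  expect_equal(imported$position, c(3027L, 3118L))
  expect_equal(imported$family_count, c(20L, 5L))
  expect_equal(imported$dcs_depth, c(10000L, 10000L))
  expect_equal(imported$time_point_hours, c(12, 24))
  expect_equal(imported$replicate, c("R6", "R6"))
  expect_error(read_variant_vcf(withr::local_tempfile(lines = c(
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "pBR322\t3027\t.\tC\tT\t.\tPASS\tDP=100"), fileext = ".vcf")), "AC=")
})

test_that("a variant table becomes a per-replicate observed series", {
  tab <- rbind(make_records(3027, 20, 1e4, hours = 12),
               make_records(3118, 10, 1e4, hours = 12),
               make_records(3030, 40, 1e4, hours = 24),
               make_records(700, 1, 1e4, hours = 36),   # flicker-only point
               make_records(3030, 99, 1e4, hours = 12, rep = "R7"))
  s <- variant_series(tab, "R6")
  expect_equal(s$generation, c(12L, 24L, 36L))
  expect_equal(s$frequency, c(0.003, 0.004, 0))
  s7 <- variant_series(tab, "R7")
  expect_equal(s7$frequency, 0.0099)
  expect_error(variant_series(tab, "R9"), "no records")
})

test_that("time conversions and growth formulas match hand arithmetic", {
  expect_equal(hours_to_generations(318), 318L)
  expect_equal(hours_to_generations(0), 0L)
  expect_equal(hours_to_generations(12, 90), 8L)
  expect_error(hours_to_generations(5, 0), "positive")

  expect_equal(max_growth_rate(36), log(4 / 3) / 36)
  expect_gt(max_growth_rate(36), 0.0071)
  expect_lt(max_growth_rate(36), 0.0092)
  t_inv <- log(4 / 3) / 0.0177
  expect_equal(max_growth_rate(t_inv), 0.0177)
  expect_equal(max_growth_rate(72), max_growth_rate(36) / 2)
  expect_error(max_growth_rate(0), "positive")

  expect_equal(generation_time(0.008), log(2) / 0.008)
  expect_equal(generation_time(log(2) / 60), 60)
  expect_equal(generation_time(0.0079), 87.74, tolerance = 1e-3)
  expect_error(generation_time(-1), "positive")
})
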