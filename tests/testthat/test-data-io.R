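test_that("BED tags parse with the 5'-end convention", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t132\tr1\t0\t+",
               "chr1\t100\t132\tr2\t0\t-"), bed)
  tags <- read_tags_set(bed, "bed")
  expect_equal(tags$pos5, c(100L, 131L))
  expect_equal(tags$strand, c("+", "-"))

  empty <- tempfile(fileext = ".bed")
  writeLines(character(0), empty)
  expect_equal(nrow(read_tags_set(empty, "bed")), 0L)

  bad <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t132\tr1\t0\t+",
               "chr1\t200\t232\tr2\t0\t*"), bad)
  expect_error(read_tags_set(bad, "bed"), "strand.*line 2")
})

test_that("SAM tags are read through the standard machinery", {
  sam <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:unsorted",
    "@SQ\tSN:chr1\tLN:100000",
    paste("r1", 0, "chr1", 101, 60, "32M", "*", 0, 0,
          paste(rep("A", 32), collapse = ""), "*", sep = "\t"),
    paste("r2", 16, "chr1", 201, 60, "32M", "*", 0, 0,
          paste(rep("A", 32), collapse = ""), "*", sep = "\t"),
    paste("r3", 4, "*", 0, 0, "*", "*", 0, 0,
          paste(rep("A", 32), collapse = ""), "*", sep = "\t")
  ), sam)
  expect_message(tags <- read_tags_set(sam, "sam"), "skipped 1")
  expect_equal(tags$pos5, c(100L, 231L))  # fwd start; rev last covered base
  expect_equal(tags$strand, c("+", "-"))
})

test_that("paired records collapse to fragments", {
  bedpe <- tempfile(fileext = ".bedpe")
  writeLines(c("chr1\t100\t132\tchr1\t240\t272\tf1",
               "chr1\t500\t532\tchr2\t600\t632\tf2",
               "chr1\t0\t1\tchr1\t0\t1\tf3"), bedpe)
  fr <- read_fragments_pet(bedpe, "bedpe")
  expect_equal(nrow(fr), 2L)
  expect_equal(fr$left[1], 100L)
  expect_equal(fr$right[1], 271L)
  expect_equal(fr$length[1], 172L)
  expect_equal(fr$length[2], 1L)   # degenerate 1-bp fragment is valid
  expect_equal(attr(fr, "n_discordant"), 1L)
  expect_true(all(fr$length == fr$right - fr$left + 1L))
})

test_that("paired SAM mates are joined by read name", {
  sam <- tempfile(fileext = ".sam")
  seq32 <- paste(rep("A", 36), collapse = "")
  writeLines(c(
    "@HD\tVN:1.6\tSO:unsorted",
    "@SQ\tSN:chr1\tLN:100000",
    paste("p1", 99, "chr1", 101, 60, "36M", "=", 241, 176, seq32, "*", sep = "\t"),
    paste("p1", 147, "chr1", 241, 60, "36M", "=", 101, -176, seq32, "*", sep = "\t"),
    paste("orphan", 99, "chr1", 301, 60, "36M", "=", 401, 136, seq32, "*", sep = "\t")
  ), sam)
  expect_warning(fr <- read_fragments_pet(sam, "sam"), "without a usable mate")
  expect_equal(nrow(fr), 1L)
  expect_equal(fr$left, 100L)
  expect_equal(fr$right, 275L)  # 1-based [241, 276] -> 0-based inclusive
})

test_that("candidate regions keep order, ids and validity", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t500\t900\tpeakA", "chr1\t800\t1200"), bed)
  rg <- read_regions_bed(bed)
  expect_equal(rg$region_id, c("peakA", "region_0002"))
  expect_equal(rg$start, c(500L, 800L))  # overlapping regions not merged
  expect_error(read_regions_bed(tempfile()), "not found")

  bad <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t500\t900", "chr1\t900\t900"), bad)
  expect_error(read_regions_bed(bad), "line 2")
})

test_that("length distribution is a normalized pmf over the window", {
  fr <- data.frame(chrom = "c", left = 0L, right = 0L,
                   length = c(150L, 150L, 200L))
  fld <- estimate_length_distribution(fr)
  expect_equal(fld$support, c(150L, 200L))
  expect_equal(fld$pmf, c(2 / 3, 1 / 3))

  fr2 <- data.frame(chrom = "c", left = 0L, right = 0L,
                    length = c(10L, 150L))
  fld2 <- estimate_length_distribution(fr2, min_len = 50)
  expect_equal(fld2$pmf, 1)
  expect_error(estimate_length_distribution(fr2, min_len = 300),
               "no fragment")
  # pmf always sums to 1 for arbitrary inputs
  for (s in 1:5) {
    set.seed(s)
    fr3 <- data.frame(chrom = "c", left = 0L, right = 0L,
                      length = sample(50:500, 40, replace = TRUE))
    expect_equal(sum(estimate_length_distribution(fr3)$pmf), 1,
                 tolerance = 1e-12)
  }
})

test_that("tags and fragments round-trip through BED dialects", {
  set.seed(3)
  tags <- data.frame(chrom = "chrT", pos5 = sample(1000:2000, 50),
                     strand = sample(c("+", "-"), 50, replace = TRUE),
                     stringsAsFactors = FALSE)
  f <- tempfile(fileext = ".bed")
  write_tags_bed(tags, f)
  back <- read_tags_set(f, "bed")
  expect_equal(back$pos5, tags$pos5)
  expect_equal(back$strand, tags$strand)

  lens <- sample(80:300, 50, replace = TRUE)
  left <- sample(5000:6000, 50)
  frag <- data.frame(chrom = "chrT", left = left, right = left + lens - 1L,
                     length = lens, stringsAsFactors = FALSE)
  f2 <- tempfile(fileext = ".bedpe")
  write_fragments_bedpe(frag, f2)
  back2 <- read_fragments_pet(f2, "bedpe")
  expect_equal(back2$left, frag$left)
  expect_equal(back2$right, frag$right)
  expect_equal(back2$length, frag$length)
})

test_that("event tables are written 1-based with a companion BED", {
  events <- data.frame(region_id = c("r1", "r1"), chrom = "chrT",
                       position = c(99L, 250L), strength = c(30, 20),
                       weight = c(0.6, 0.4), G_selected = 2L, bic = 123.4,
                       stringsAsFactors = FALSE)
  out <- tempfile(fileext = ".tsv")
  write_events(events, out)
  tab <- read.table(out, header = TRUE, sep = "\t")
  expect_equal(tab$position, c(100L, 251L))
  expect_equal(nrow(tab), 2L)
  bed <- read.table(paste0(out, ".bed"), sep = "\t")
  expect_equal(bed$V2, c(99L, 250L))
  expect_equal(bed$V3 - bed$V2, c(1L, 1L))

  empty <- events[0, ]
  out2 <- tempfile(fileext = ".tsv")
  write_events(empty, out2)
  expect_equal(nrow(read.table(out2, header = TRUE, sep = "\t")), 0L)
})

test_that("reads are assigned to flank-extended regions", {
  region <- test_region(1000L, 1500L)
  tags <- data.frame(chrom = "chrT", pos5 = c(850L, 999L, 1499L, 1700L),
                     strand = "+", stringsAsFactors = FALSE)
  expect_equal(nrow(assign_to_region(tags, region, "set", flank = 0L)), 1L)
  expect_equal(nrow(assign_to_region(tags, region, "set", flank = 200L)), 3L)
  expect_equal(nrow(assign_to_region(tags, region, "set", flank = 201L)), 4L)
  frag <- data.frame(chrom = "chrT", left = c(700L, 700L),
                     right = c(950L, 1050L), length = c(251L, 351L))
  expect_equal(nrow(assign_to_region(frag, region, "pet", flank = 0L)), 1L)
  expect_equal(nrow(assign_to_region(frag, region, "pet", flank = 100L)), 2L)
})
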