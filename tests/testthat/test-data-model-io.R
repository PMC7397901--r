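test_that("annotation TSV parses rows, preserves unknown terms, and round-trips", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "gene_id\tlocations\treliability\trim\tmitotic_recruitment",
    "G1\tnucleoli;cytosol\tsupported\tFalse\tearly",
    "G2\tnucleoli;nucleoli_rim\tenhanced\tTrue\tnone"), path)
  ann <- read_annotation_table(path)
  expect_s3_class(ann, "protein_annotation")
  expect_equal(nrow(ann), 2L)
  expect_setequal(ann$locations[[1]], c("nucleoli", "cytosol"))
  expect_true(ann$rim[2])
  expect_true(all(is.na(ann$pan_dependent)))

  # empty file with header only -> empty table
  writeLines("gene_id\tlocations\treliability\trim\tmitotic_recruitment", path)
  expect_equal(nrow(read_annotation_table(path)), 0L)

  # unknown vocabulary warns but survives
  writeLines(c(
    "gene_id\tlocations\treliability\trim\tmitotic_recruitment",
    "G1\tnucleoli;weird_place\tapproved\tFalse\tnone"), path)
  expect_warning(ann <- read_annotation_table(path), "weird_place")
  expect_true("weird_place" %in% ann$locations[[1]])

  # round-trip reproduces records exactly
  cfg <- synthetic_config(seed = 5)
  ann <- gen_annotations(cfg)
  out <- withr::local_tempfile(fileext = ".tsv")
  write_annotation_table(ann, out)
  back <- read_annotation_table(out)
  expect_equal(as.data.frame(back), as.data.frame(ann))
})

test_that("annotation reader rejects duplicates, missing columns, rim mismatch", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "gene_id\tlocations\treliability\trim\tmitotic_recruitment",
    "G1\tnucleoli\tsupported\tFalse\tnone",
    "G1\tcytosol\tapproved\tFalse\tnone"), path)
  expect_error(read_annotation_table(path), "duplicate gene_id.*G1")

  writeLines(c("gene_id\tlocations\trim",
               "G1\tnucleoli\tFalse"), path)
  expect_error(read_annotation_table(path), "missing mandatory column.*reliability")

  writeLines(c(
    "gene_id\tlocations\treliability\trim\tmitotic_recruitment",
    "G1\tnucleoli\tsupported\tTrue\tnone"), path)
  expect_error(read_annotation_table(path), "nucleoli_rim")
})

test_that("disorder score reader parses IUPred2A long format and validates bounds", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# IUPred2A long", "1\tM\t0.1", "2\tK\t0.6", "3\tI\t0.9"), path)
  prof <- read_disorder_scores(path, gene_id = "P1")
  expect_s3_class(prof, "disorder_profile")
  expect_equal(prof$scores, c(0.1, 0.6, 0.9))
  expect_equal(length(prof), 3L)

  writeLines(c("# only", "# comments"), path)
  expect_error(read_disorder_scores(path), "no residues")

  writeLines(c("1\tM\t0.1", "2\tK\t1.2"), path)
  expect_error(read_disorder_scores(path), "outside \\[0, 1\\]")

  writeLines(c("1\tM\t0.1", "3\tK\t0.2"), path)
  expect_error(read_disorder_scores(path), "contiguous")
})

test_that("disorder reader rejects fuzz-perturbed out-of-bounds profiles", {
  path <- withr::local_tempfile(fileext = ".txt")
  withr::with_seed(11, {
    for (rep in 1:20) {
      n <- sample(5:40, 1)
      sc <- round(runif(n), 4)
      bad <- sample(n, 1)
      sc[bad] <- sample(c(-1, 2), 1) * runif(1, 1.01, 5)
      writeLines(sprintf("%d\tA\t%.4f", seq_len(n), sc), path)
      expect_error(read_disorder_scores(path))
    }
  })
  # write/read round trip on a clean profile
  prof <- disorder_profile("P9", c(0.12, 0.55, 0.99, 0))
  write_disorder_scores(prof, path)
  back <- read_disorder_scores(path, gene_id = "P9")
  expect_equal(back$scores, prof$scores, tolerance = 1e-4)
})

test_that("image pairs read from disk are dtype-scaled and shape-checked", {
  d <- withr::local_tempdir()
  dapi <- matrix(runif(256 * 256), 256, 256)
  prot <- matrix(runif(256 * 256), 256, 256)
  f1 <- file.path(d, "dapi.tif"); f2 <- file.path(d, "prot.tif")
  write_channel(dapi, f1, bits = 16L)
  write_channel(prot, f2, bits = 16L)
  pair <- read_image_pair(f1, f2, "WT", "metaphase", gene_id = "G")
  expect_equal(dim(pair$dapi), c(256L, 256L))
  expect_lte(max(pair$dapi), 1)
  expect_equal(pair$dapi, dapi, tolerance = 1e-4)

  # 8-bit PNG with all pixels at the dtype maximum reads as all 1.0
  f3 <- file.path(d, "ones.png")
  write_channel(matrix(1, 64, 64), f3, bits = 8L)
  pair2 <- read_image_pair(f3, f3, "KO", "prometaphase")
  expect_true(all(pair2$protein == 1))

  # shape mismatch
  f4 <- file.path(d, "small.tif")
  write_channel(matrix(runif(128 * 128), 128, 128), f4)
  expect_error(read_image_pair(f1, f4, "WT", "metaphase"), "identical shape")

  # multi-channel input is rejected
  f5 <- file.path(d, "rgb.png")
  EBImage::writeImage(EBImage::rgbImage(
    EBImage::Image(dapi), EBImage::Image(prot), EBImage::Image(dapi)), f5)
  expect_error(read_image_pair(f5, f5, "WT", "metaphase"), "multi-channel")
})

test_that("embedding, abundance, and survival tables round-trip with validation", {
  d <- withr::local_tempdir()
  emb <- gen_embeddings(synthetic_config(seed = 2))
  f <- file.path(d, "emb.tsv")
  write_embedding_table(emb, f)
  expect_equal(as.data.frame(read_embedding_table(f)), as.data.frame(emb),
               tolerance = 1e-12)

  ab <- gen_abundance_table(synthetic_config(seed = 2), 20, 30)
  f <- file.path(d, "ab.tsv")
  write_abundance_table(ab, f)
  expect_identical(read_abundance_table(f)$copies_per_cell, ab$copies_per_cell)

  sv <- gen_survival_cohort(synthetic_config(seed = 2), 50)
  f <- file.path(d, "sv.tsv")
  write_survival_table(sv, f)
  expect_equal(as.data.frame(read_survival_table(f)), as.data.frame(sv),
               tolerance = 1e-6)

  writeLines(c("time\tevent\texpression", "-1\t1\t5"), f)
  expect_error(read_survival_table(f), "positive")
})
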