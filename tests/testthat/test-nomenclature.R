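# Lipid shorthand parsing, class sets, TAG categories, PUFA selection.

test_that("shorthand names parse to the expected classes, chains and totals", {
  cases <- list(
    list("PC 18:0_22:6", class = "PC", C = 40L, D = 6L, sum = FALSE, nch = 2L),
    list("PC 40:6", class = "PC", C = 40L, D = 6L, sum = TRUE, nch = 0L),
    list("PC 16:0/16:0", class = "PC", C = 32L, D = 0L, sum = FALSE, nch = 2L),
    list("PE O-18:1_22:5", class = "O-PE", C = 40L, D = 6L, sum = FALSE, nch = 2L),
    list("TAG 48:0", class = "TAG", C = 48L, D = 0L, sum = TRUE, nch = 0L),
    list("SM d42:2", class = "SM", C = 42L, D = 2L, sum = TRUE, nch = 0L),
    list("Car 24:1", class = "Car", C = 24L, D = 1L, sum = FALSE, nch = 1L),
    list("Cer C23:0", class = "Cer", C = 23L, D = 0L, sum = FALSE, nch = 1L),
    list("LPC 18:1(d7)", class = "LPC", C = 18L, D = 1L, sum = FALSE, nch = 1L))
  for (cs in cases) {
    a <- parse_lipid_name(cs[[1]])
    expect_identical(a$lipid_class, cs$class, label = cs[[1]])
    expect_identical(a$total_carbons, cs$C, label = cs[[1]])
    expect_identical(a$total_double_bonds, cs$D, label = cs[[1]])
    expect_identical(a$sum_level_only, cs$sum, label = cs[[1]])
    expect_length(a$chains, cs$nch)
  }
  expect_true(parse_lipid_name("LPC 18:1(d7)")$is_istd)
  expect_identical(parse_lipid_name("LPC 18:1(d7)")$isotope_label, "d7")
  expect_true(parse_lipid_name("PC 16:0/16:0")$sn_known)
  expect_false(parse_lipid_name("PC 18:0_22:6")$sn_known)
  # when chains are known, the totals are their sums
  a <- parse_lipid_name("TAG 15:0_18:1_15:0(d7)")
  expect_identical(a$total_carbons, 48L)
  expect_identical(a$total_double_bonds, 1L)
})

test_that("figure-style name list parses without error and round-trips", {
  names <- c("PC 18:0_22:6", "PE 18:0_22:6", "PC 40:6", "PC 16:0/16:0",
             "PE O-18:1_22:5", "PE 18:0_22:5", "SM d42:2", "Car 24:1",
             "Car 24:0", "Car 26:1", "Cer C16:0", "Cer C18:0", "Cer C23:0",
             "Cer C24:0", "Cer C24:1", "Cer C25:0", "TAG 48:0", "TAG 50:2",
             "TAG 56:6", "TAG 58:8", "LPC 18:1", "LPC 18:1(d7)", "LPE 18:1",
             "PC 15:0_18:1(d7)", "PE 15:0_18:1(d7)", "PS 15:0_18:1(d7)",
             "PG 15:0_18:1(d7)", "PI 15:0_18:1(d7)", "CE 18:1(d7)",
             "DAG 15:0_18:1(d7)", "SM d36:1(d9)", "HexCer d36:1", "PI 38:4",
             "PG 34:1", "PS 40:6", "FFA 18:2", "FFA 22:6", "NAE 16:0",
             "DAG 36:2", "O-PC 34:1", "PC 16:0_20:4", "PE 16:0_22:6")
  for (nm in names) {
    a <- expect_no_error(parse_lipid_name(nm))
    # chain-resolved and sum-level forms round-trip to an identical structure
    b <- parse_lipid_name(format_lipid_name(a))
    b$raw_name <- a$raw_name
    expect_identical(b, a, label = nm)
  }
})

test_that("unparseable names raise a parse error naming the token", {
  err <- tryCatch(parse_lipid_name("XYZ 18:1"), error = identity)
  expect_s3_class(err, "lipid_parse_error")
  expect_identical(err$token, "XYZ")
  err <- tryCatch(parse_lipid_name("PC foo"), error = identity)
  expect_identical(err$token, "foo")
  expect_error(parse_lipid_name("PC 18:40"), class = "lipid_parse_error")
})

test_that("MSI level 4 features carry no class and never a fallback class", {
  a <- parse_lipid_name("unknown_017", msi_level = 4)
  expect_true(is.na(a$lipid_class))
  expect_identical(a$msi_level, 4L)
})

test_that("class sets honour the minimal size and exclude unknowns", {
  ann <- data.frame(
    feature_id = sprintf("f%02d", 1:16),
    name = c(sprintf("PC %d:1", 30:41), sprintf("PS %d:1", 34:36), "unknown_1"),
    msi_level = c(rep(2L, 15), 4L))
  parsed <- parse_lipid_annotations(ann)
  cat10 <- build_class_sets(parsed, min_size = 10)
  expect_named(cat10$sets, "PC")
  expect_length(cat10$sets$PC, 12L)
  cat1 <- build_class_sets(parsed, min_size = 1)
  expect_setequal(names(cat1$sets), c("PC", "PS"))
  # unknowns never enter a set; class sets are disjoint and cover MSI<=3 once
  all_members <- unlist(cat1$sets)
  expect_false("f16" %in% all_members)
  expect_identical(anyDuplicated(all_members), 0L)
  expect_setequal(all_members, parsed$feature_id[parsed$msi_level <= 3])
  expect_error(build_class_sets(parsed[0, ]), "empty")
})

test_that("TAG species fall in the quoted saturation and chain-length bins", {
  got <- assign_tag_category(c(50, 48, 56, 30, 49, 52, 53, 55, 60, 62),
                             c(2, 0, 6, 1, 2, 3, 0, 9, 8, 2))
  expect_identical(got$saturation[1:3],
                   c("polyunsaturated", "saturated", "polyunsaturated"))
  expect_identical(got$chain_length,
                   c("medium-chain", "short-chain", "very-long-chain",
                     "short-chain", "medium-chain", "medium-chain",
                     "long-chain", "long-chain", "very-long-chain", "other"))
  expect_identical(got$flagged, c(rep(FALSE, 9), TRUE))
})

test_that("PUFA selection pairs an anchor with the target chain and skips sum-level species", {
  feats <- data.frame(
    feature_id = paste0("f", 1:7),
    name = c("PC 16:0_20:4", "PC 18:0_22:6", "PC 17:0_20:4", "PC 40:6",
             "PE 16:1_22:6", "PE O-18:1_22:5", "Car 20:4"),
    msi_level = 2L)
  ann <- parse_lipid_annotations(feats)
  sel <- select_pufa_species(ann)
  expect_setequal(sel$feature_id[sel$target == "20:4"], "f1")   # ARA set
  expect_setequal(sel$feature_id[sel$target == "22:6"], c("f2", "f5"))  # DHA set
  expect_false("f3" %in% sel$feature_id)  # 17:0 is not an anchor
  expect_false("f7" %in% sel$feature_id)  # class restriction
  expect_identical(attr(sel, "skipped"), "f4")  # sum-level PC reported
})

test_that("annotation tables round-trip through TSV", {
  path <- system.file("extdata", "example_annotations.tsv",
                      package = "lipidcourse")
  ann <- read_annotation_table(path)
  expect_gt(nrow(ann), 30)
  expect_true(all(is.na(ann$lipid_class) == (ann$msi_level == 4L)))
  tmp <- tempfile(fileext = ".tsv")
  write_annotation_table(ann, tmp)
  again <- read_annotation_table(tmp)
  expect_identical(again$name, ann$name)
  expect_identical(again$total_carbons, ann$total_carbons)
})
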