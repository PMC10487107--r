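test_that("empty index annotates everything intergenic and non-Alu", {
  idx <- build_annotation_index(NULL, NULL)
  sites <- make_sites(edits = c(1L, 2L), reads = c(10L, 10L),
                      position = c(50L, 5000L))
  ann <- annotate_sites(sites, idx)
  expect_equal(ann$region_class, c("intergenic", "intergenic"))
  expect_equal(ann$in_alu, c(FALSE, FALSE))
})

test_that("fixture geometry annotates with documented precedence", {
  w <- fixture_annotation_world()
  idx <- build_annotation_index(w$genes, w$alu)
  sites <- make_sites(edits = rep(2L, 7L), reads = rep(10L, 7L),
                      position = c(120L,   # utr5 (inside exon: utr5 wins)
                                   170L,   # exon outside UTRs -> exonic_cds
                                   350L,   # intron, inside AluIntronic
                                   590L,   # utr3 (inside last exon)
                                   850L,   # intergenic, inside Alu
                                   1050L,  # noncoding gene exon
                                   1200L)) # noncoding gene intron
  ann <- annotate_sites(sites, idx)
  expect_equal(ann$region_class,
               c("utr5", "exonic_cds", "intronic", "utr3", "intergenic",
                 "noncoding_or_RNA", "noncoding_or_RNA"))
  expect_equal(ann$in_alu,
               c(FALSE, FALSE, TRUE, FALSE, TRUE, FALSE, FALSE))
  ## annotation never alters counts or ratios
  expect_equal(ann$edit_count, sites$edit_count)
  expect_equal(ann$edit_ratio, sites$edit_ratio)
})

test_that("index queries equal a brute-force scan on 1,000 random intervals", {
  set.seed(601)
  n <- 1000L
  starts <- sample.int(50000L, n)
  ends <- starts + sample.int(400L, n, replace = TRUE)
  alu <- data.table(contig = "chrT", start = starts, end = ends,
                    label = sprintf("iv%04d", seq_len(n)))
  idx <- build_annotation_index(NULL, alu)
  pts <- sample.int(51000L, 200L)
  sites <- make_sites(edits = rep(1L, 200L), reads = rep(4L, 200L),
                      position = pts)
  ann <- annotate_sites(sites, idx)
  brute <- vapply(pts, function(p)
    length(oracle_point_overlap(p, starts, ends)) > 0L, logical(1L))
  expect_equal(ann$in_alu, brute)
})

test_that("summarize_by_region reproduces a brute-force group-by", {
  ## tiny arithmetic case first
  s <- make_sites(edits = c(1L, 4L), reads = c(10L, 20L), position = 1:2)
  s$region_class <- "intronic"; s$in_alu <- FALSE
  sm <- summarize_by_region(s)
  row <- sm[region_class == "intronic" & in_alu == FALSE]
  expect_equal(row$n_sites, 2L)
  expect_equal(row$mean_reads, 15)
  expect_equal(row$mean_edits, 2.5)
  expect_equal(row$mean_ratio, 0.15)
  expect_equal(sm[region_class == "utr3", sum(n_sites)], 0L)
  expect_equal(sum(sm$n_sites), nrow(s))   # classes partition the sites

  ## randomized 500-site fixture vs independent aggregate
  set.seed(602)
  big <- random_sites(500)
  big$region_class <- sample(c("utr3", "utr5", "exonic_cds",
                               "noncoding_or_RNA", "intronic",
                               "intergenic"), 500, replace = TRUE)
  big$in_alu <- sample(c(TRUE, FALSE), 500, replace = TRUE)
  sm <- summarize_by_region(big)
  expect_equal(sum(sm$n_sites), 500L)
  by_hand <- aggregate(cbind(total_reads, edit_count, edit_ratio) ~
                         region_class + in_alu, data = big, FUN = mean)
  for (i in seq_len(nrow(by_hand))) {
    row <- sm[region_class == by_hand$region_class[i] &
                in_alu == by_hand$in_alu[i]]
    expect_equal(row$mean_reads, by_hand$total_reads[i])
    expect_equal(row$mean_edits, by_hand$edit_count[i])
    expect_equal(row$mean_ratio, by_hand$edit_ratio[i])
  }

  expect_error(summarize_by_region(make_sites(1L, 10L)), "annotate")
})

test_that("site_set_comparison tallies unique and shared site keys", {
  s1 <- make_sites(edits = c(1L, 2L), reads = c(10L, 10L), position = 1:2)
  s2 <- make_sites(edits = c(2L, 3L), reads = c(10L, 10L), position = 2:3)
  res <- site_set_comparison(list(A = s1, B = s2))
  expect_equal(unname(res$unique_counts), c(1L, 1L))
  expect_equal(res$shared_count, 1L)

  same <- site_set_comparison(list(A = s1, B = copy(s1)))
  expect_equal(unname(same$unique_counts), c(0L, 0L))
  expect_equal(same$shared_count, 2L)

  expect_error(site_set_comparison(list(A = s1)), "two groups")

  ## 3 random groups vs brute-force membership enumeration
  set.seed(603)
  groups <- lapply(1:3, function(i) random_sites(40))
  res <- site_set_comparison(setNames(groups, c("g1", "g2", "g3")))
  keys <- lapply(groups, function(g)
    unique(paste(g$contig, g$position, g$edit_type, sep = ":")))
  all_keys <- unique(unlist(keys))
  n_member <- vapply(all_keys, function(k)
    sum(vapply(keys, function(kk) k %in% kk, logical(1L))), integer(1L))
  expect_equal(res$shared_count, sum(n_member > 1L))
  for (i in 1:3)
    expect_equal(unname(res$unique_counts[i]),
                 sum(keys[[i]] %in% all_keys[n_member == 1L]))
})
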