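gene_df <- function(starts, ends, strands, contig = "c1",
                    ids = sprintf("g%02d", seq_along(starts))) {
  data.frame(gene_id = ids, contig_id = contig, start = starts, end = ends,
             strand = strands, stringsAsFactors = FALSE)
}

test_that("operon chaining applies the strict <100 bp same-strand rule", {
  g <- gene_df(c(0, 1050), c(1000, 2000), c("+", "+"))
  op <- infer_operons(g, gap_max = 100)
  expect_equal(length(unique(op$operon_id)), 1L)   # gap 50 -> one operon

  g2 <- gene_df(c(0, 1100), c(1000, 2000), c("+", "+"))
  op2 <- infer_operons(g2, gap_max = 100)
  expect_equal(length(unique(op2$operon_id)), 2L)  # gap exactly 100 -> split

  g3 <- gene_df(c(0, 1050), c(1000, 2000), c("+", "-"))
  expect_equal(length(unique(infer_operons(g3)$operon_id)), 2L)  # strand switch
})

test_that("operon partition matches the chain-scan oracle on a mixed contig", {
  set.seed(7)
  starts <- cumsum(c(100, sample(c(30, 80, 150, 400), 19, replace = TRUE) +
                       sample(600:1200, 19, replace = TRUE)))
  ends <- starts + sample(600:1200, 20, replace = TRUE)
  strands <- sample(c("+", "-"), 20, replace = TRUE)
  g <- gene_df(starts, pmin(ends, starts + 900), strands)
  op <- infer_operons(g, gap_max = 100)
  canon <- function(lst) {
    lst <- unname(lapply(lst, sort))
    lst[order(vapply(lst, `[`, "", 1))]
  }
  got <- split(op$gene_id, op$operon_id)
  want <- oracle_operons(g, gap_max = 100)
  expect_equal(canon(got), canon(want))
  # every gene in exactly one operon, all within-operon gaps < 100
  expect_equal(sort(op$gene_id), sort(g$gene_id))
  for (members in got) {
    gg <- g[g$gene_id %in% members, ]
    gg <- gg[order(gg$start), ]
    if (nrow(gg) > 1) expect_true(all(gg$start[-1] - gg$end[-nrow(gg)] < 100))
  }
})

test_that("promoter windows cover -upstream..+downstream of the start, clipped", {
  expect_equal(c(promoter_window(1000, 1600, "+", 300, 50, 5000)),
               c(700, 1050))
  expect_equal(c(promoter_window(400, 1000, "-", 300, 50, 5000)),
               c(950, 1300))
  expect_equal(c(promoter_window(100, 700, "+", 300, 50, 5000)),
               c(0, 150))
  expect_equal(c(promoter_window(4000, 4900, "-", 300, 50, 5000)),
               c(4850, 5000))
  # length <= upstream + downstream, with equality away from edges
  set.seed(3)
  st <- sample(0:4000, 50); en <- st + 500
  w <- promoter_window(st, en, sample(c("+", "-"), 50, TRUE), 300, 50, 4600)
  expect_true(all(w[, 2] - w[, 1] <= 350))
})

test_that("sites link to the gene with the nearest translational start", {
  genes <- gene_df(c(1000, 3000), c(2000, 4000), c("+", "+"))
  hits <- data.frame(contig_id = "c1", start = 892, end = 908, strand = "+",
                     score = 15, site_seq = "X", stringsAsFactors = FALSE)
  lk <- link_sites_to_genes(hits, genes)
  expect_equal(lk$gene_id, "g01")
  expect_equal(lk$distance_to_start, -100)
  expect_true(lk$in_promoter)
})

test_that("distance ties break toward the promoter-containing, then lower gene", {
  # midpoint equidistant between g1 start (1000, +) and g2 TSS (1199, -)
  genes <- gene_df(c(1000, 1100), c(1090, 1200), c("+", "-"))
  hits <- data.frame(contig_id = "c1", start = 1091, end = 1107, strand = "+",
                     score = 15, site_seq = "X", stringsAsFactors = FALSE)
  # mid = 1099; d(g1) = 99, d(g2) = 100 -> no tie, sanity
  expect_equal(link_sites_to_genes(hits, genes)$gene_id, "g01")
  # construct an exact tie: two + genes, site midway between their starts
  genes2 <- gene_df(c(1000, 1400), c(1300, 1800), c("+", "+"))
  hits2 <- data.frame(contig_id = "c1", start = 1192, end = 1208, strand = "+",
                      score = 15, site_seq = "X", stringsAsFactors = FALSE)
  # mid = 1200, d = 200 both; inside g2's window [1100,1450) and g1's
  # [700,1050)? no -> g2 wins by the promoter clause
  lk2 <- link_sites_to_genes(hits2, genes2)
  expect_equal(lk2$gene_id, "g02")
  # both-in-promoter tie -> lower-coordinate gene
  genes3 <- gene_df(c(1000, 1400), c(1300, 1800), c("+", "+"))
  hits3 <- data.frame(contig_id = "c1", start = 1192, end = 1208, strand = "+",
                      score = 15, site_seq = "X", stringsAsFactors = FALSE)
  lk3 <- link_sites_to_genes(hits3, genes3, upstream = 300, downstream = 210)
  expect_equal(lk3$gene_id, "g01")
})

test_that("linking matches the all-pairs oracle on a 50-site fixture", {
  set.seed(13)
  g <- gene_df(starts = sort(sample(seq(0, 28000, by = 40), 30)),
               ends = NA, strands = sample(c("+", "-"), 30, TRUE))
  g$end <- g$start + sample(400:900, 30, replace = TRUE)
  s0 <- sample(0:29000, 50)
  hits <- data.frame(contig_id = "c1", start = s0, end = s0 + 16,
                     strand = sample(c("+", "-"), 50, TRUE),
                     score = runif(50, 9, 20), site_seq = "X",
                     stringsAsFactors = FALSE)
  hits <- hits[order(hits$start), ]
  lk <- link_sites_to_genes(hits, g, contig_lens = c(c1 = 30000))
  orc <- oracle_link(hits, g, contig_len = 30000)
  expect_equal(lk$gene_id, orc$gene_id)
  expect_equal(lk$distance_to_start, orc$distance)
  expect_equal(lk$in_promoter, orc$in_promoter)
})

test_that("sites on geneless contigs are dropped and counted", {
  genes <- gene_df(1000, 2000, "+")
  hits <- data.frame(contig_id = c("c1", "c9"), start = c(892, 10),
                     end = c(908, 26), strand = "+", score = 15,
                     site_seq = "X", stringsAsFactors = FALSE)
  lk <- link_sites_to_genes(hits, genes)
  expect_equal(nrow(lk), 1L)
  expect_equal(attr(lk, "n_dropped_no_gene"), 1L)
})

test_that("promoter filtering keeps upstream sites and drops mid-gene ones", {
  genes <- gene_df(1000, 3000, "+")
  hits <- data.frame(contig_id = "c1", start = c(892, 1992), end = c(908, 2008),
                     strand = "+", score = 15, site_seq = "X",
                     stringsAsFactors = FALSE)
  lk <- link_sites_to_genes(hits, genes)
  kept <- filter_promoter_sites(lk)
  expect_equal(kept$start, 892)
  expect_equal(nrow(filter_promoter_sites(lk[lk$start == 1992, ])), 0L)
})

test_that("gene tables round-trip through 1-based TSV and GFF3", {
  g <- gene_df(c(999, 2999), c(2000, 4000), c("+", "-"))
  g$cog_id <- c("COG0001", ""); g$cog_category <- c("L", "")
  g$phylum <- c("Firmicutes", "Bacteroidetes")
  tsv <- tempfile(fileext = ".tsv")
  write_gene_table(g, tsv)
  g2 <- read_gene_table(tsv)
  expect_equal(g2$start, g$start)
  expect_equal(g2$end, g$end)
  expect_equal(g2$cog_id, g$cog_id)

  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               paste("c1", "test", "gene", 1000, 2000, ".", "+", ".",
                     "ID=g01;cog_id=COG0001;cog_category=L;phylum=Firmicutes",
                     sep = "\t")), gff)
  g3 <- read_genes_gff3(gff)
  expect_equal(g3$start, 999)
  expect_equal(g3$end, 2000)
  expect_equal(g3$cog_id, "COG0001")
  expect_equal(g3$phylum, "Firmicutes")
})
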