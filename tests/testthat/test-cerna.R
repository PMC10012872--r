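# ceRNA triple construction, the sign-consistency filter, and network export.

test_that("triples require shared-miRNA sites on both sides and DE membership", {
  sites <- rbind(site_stub("mir1", "circ1", "circRNA"),
                 site_stub("mir1", "geneA", "mRNA_3UTR"),
                 site_stub("mir2", "circ2", "circRNA"))  # no mRNA side
  de <- list(circrna = de_stub(c("circ1", "circ2"), c("down", "up")),
             mirna = de_stub(c("mir1", "mir2"), c("up", "down")),
             mrna = de_stub("geneA", "down"),
             lncrna = de_stub(character(0), character(0)))
  tri <- find_triples(sites, de)
  expect_equal(nrow(tri), 1)
  expect_equal(tri$sponge, "circ1")
  expect_equal(tri$mirna, "mir1")
  expect_equal(tri$mrna, "geneA")
  expect_equal(c(tri$dir_sponge, tri$dir_mirna, tri$dir_mrna),
               c("down", "up", "down"))
  expect_error(find_triples(sites, de[c("circrna", "mrna")]), "mirna")
})

test_that("non-DE members exclude a triple", {
  sites <- rbind(site_stub("mir1", "circ1", "circRNA"),
                 site_stub("mir1", "geneA", "mRNA_3UTR"))
  de <- list(circrna = de_stub("circ1", "ns"),
             mirna = de_stub("mir1", "up"),
             mrna = de_stub("geneA", "down"))
  expect_equal(nrow(find_triples(sites, de)), 0)
})

test_that("multiple sites are counted per triple side", {
  sites <- rbind(site_stub("mir1", "circ1", "circRNA", 10L),
                 site_stub("mir1", "circ1", "circRNA", 100L),
                 site_stub("mir1", "circ1", "circRNA", 200L),
                 site_stub("mir1", "geneA", "mRNA_3UTR", 50L))
  de <- list(circrna = de_stub("circ1", "down"),
             mirna = de_stub("mir1", "up"),
             mrna = de_stub("geneA", "down"))
  tri <- find_triples(sites, de)
  expect_equal(tri$n_sites_sponge, 3L)
  expect_equal(tri$n_sites_mrna, 1L)
})

test_that("triples equal a brute-force join oracle on a synthetic run", {
  cfg <- sim_config(seed = 5)
  sim <- simulate_sequences(cfg)
  cm <- simulate_counts(sim$truth, cfg)
  de <- lapply(stats::setNames(nm = c("mrna", "lncrna", "circrna", "mirna")),
               function(cls) de_analysis(cm[[cls]], cm$design, de_profile(cls)))
  de_feat <- function(cls) de[[cls]]$feature[de[[cls]]$direction != "ns"]
  mir <- sim$sequences$mirna[intersect(names(sim$sequences$mirna), de_feat("mirna"))]
  sites <- rbind(
    predict_targets(mir, sim$sequences$circrna[
      intersect(names(sim$sequences$circrna), de_feat("circrna"))], "circRNA"),
    predict_targets(mir, sim$sequences$lncrna[
      intersect(names(sim$sequences$lncrna), de_feat("lncrna"))], "lncRNA"),
    predict_targets(mir, sim$sequences$mrna[
      intersect(names(sim$sequences$mrna), de_feat("mrna"))], "mRNA_3UTR"))
  tri <- find_triples(sites, de)

  # oracle: nested loops over all DE sponge/miRNA/mRNA combinations
  oracle <- list()
  sponges <- c(de_feat("circrna"), de_feat("lncrna"))
  for (s in sponges) for (m in de_feat("mirna")) for (g in de_feat("mrna")) {
    has_sp <- any(sites$mirna == m & sites$target == s)
    has_mr <- any(sites$mirna == m & sites$target == g &
                    sites$target_class == "mRNA_3UTR")
    if (has_sp && has_mr) oracle[[length(oracle) + 1]] <- paste(s, m, g)
  }
  expect_setequal(paste(tri$sponge, tri$mirna, tri$mrna), unlist(oracle))
})

test_that("exactly two of the eight direction triplets conform to the mechanism", {
  dirs <- expand.grid(s = c("up", "down"), m = c("up", "down"),
                      g = c("up", "down"), stringsAsFactors = FALSE)
  tri <- data.frame(sponge = paste0("c", 1:8), sponge_class = "circRNA",
                    mirna = paste0("m", 1:8), mrna = paste0("g", 1:8),
                    dir_sponge = dirs$s, dir_mirna = dirs$m, dir_mrna = dirs$g,
                    n_sites_sponge = 1L, n_sites_mrna = 1L,
                    stringsAsFactors = FALSE)
  kept <- mechanism_filter(tri)
  expect_equal(nrow(kept), 2)
  pats <- paste(kept$dir_sponge, kept$dir_mirna, kept$dir_mrna)
  expect_setequal(pats, c("up down up", "down up down"))
})

test_that("the mechanism filter is idempotent, subsetting, and order-invariant", {
  tri <- data.frame(sponge = c("c1", "c2", "c3"), sponge_class = "circRNA",
                    mirna = c("m1", "m2", "m3"), mrna = c("g1", "g2", "g3"),
                    dir_sponge = c("down", "down", "up"),
                    dir_mirna = c("up", "down", "ns"),
                    dir_mrna = c("down", "down", "up"),
                    n_sites_sponge = 1L, n_sites_mrna = 1L,
                    stringsAsFactors = FALSE)
  expect_message(kept <- mechanism_filter(tri), "ns")
  expect_equal(kept$sponge, "c1")
  expect_true(all(kept$mechanism_pass))
  again <- mechanism_filter(kept)
  expect_equal(again$sponge, kept$sponge)
  perm <- mechanism_filter(tri[c(3, 1, 2), ])
  expect_setequal(perm$sponge, kept$sponge)
})

test_that("network export deduplicates edges and tallies nodes by class", {
  tri <- data.frame(sponge = c("c1", "c2"), sponge_class = "circRNA",
                    mirna = c("m1", "m1"), mrna = c("g1", "g1"),
                    dir_sponge = "down", dir_mirna = "up", dir_mrna = "down",
                    n_sites_sponge = 1L, n_sites_mrna = 1L,
                    stringsAsFactors = FALSE)
  net <- export_network(tri[1, ])
  expect_equal(nrow(net$edges), 2)   # one triple -> 2 edges, 3 nodes
  expect_equal(nrow(net$nodes), 3)
  net2 <- export_network(tri)        # shared miRNA-mRNA edge emitted once
  expect_equal(nrow(net2$edges), 3)
  expect_equal(sum(net2$edges$edge_type == "miRNA-mRNA"), 1)
  expect_equal(sum(net2$nodes$class == "circRNA"), 2)
  expect_equal(sum(net2$nodes$class == "miRNA"), 1)
  expect_equal(sum(net2$nodes$class == "mRNA"), 1)
})
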