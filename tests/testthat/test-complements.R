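sp_abc <- parse_newick("((A:1,B:1)AB:1,C:2)R;")
sp <- fixture_species_tree()

lm_auto <- function(gt, spt) leaf_species_map(gt, spt, "_", "prefix")

test_that("copy_numbers follows the lineage-propagation convention", {
  # congruent single-copy family: N = 1 everywhere at/below the origin
  gt <- parse_newick("((A_1,B_1)x,C_1)r;")
  N <- copy_numbers(reconcile(gt, sp_abc, lm_auto(gt, sp_abc)))
  expect_true(all(N == 1L))

  # one duplication at AB, no losses
  gt2 <- parse_newick("(((A_1,B_1)x,(A_2,B_2)y)d,C_1)r;")
  N2 <- copy_numbers(reconcile(gt2, sp_abc, lm_auto(gt2, sp_abc)))
  expect_equal(unname(N2[c("R", "AB", "A", "B", "C")]),
               c(1L, 2L, 2L, 2L, 1L))

  # family restricted to one species: zero outside the origin subtree
  gt3 <- parse_newick("(A_1,A_2)d;")
  N3 <- copy_numbers(reconcile(gt3, sp_abc, lm_auto(gt3, sp_abc)))
  expect_equal(unname(N3[c("A", "B", "C", "AB", "R")]),
               c(2L, 0L, 0L, 0L, 0L))
})

test_that("copy_numbers equals event-log replay on simulated families", {
  for (s in 1:150) {
    fam <- simulate_family(sp, sim_params(0.5, 0.2, seed = 7000 + s))
    if (fam$extinct) next
    rec <- reconcile(fam$gene_tree, sp, lm_auto(fam$gene_tree, sp))
    expect_identical(unname(copy_numbers(rec)),
                     unname(as.integer(replay_complement(fam))))
  }
})

test_that("leaf conservation and edge balance hold on all instances", {
  sx <- famrecon:::species_index(sp)
  for (s in 1:60) {
    fam <- simulate_family(sp, sim_params(0.6, 0.3, seed = 8000 + s))
    if (fam$extinct) next
    rec <- reconcile(fam$gene_tree, sp, lm_auto(fam$gene_tree, sp))
    N <- copy_numbers(rec)
    lm <- table(lm_auto(fam$gene_tree, sp))
    for (spp in sp$tip.label) {
      expect_identical(unname(N[spp]),
                       if (spp %in% names(lm)) as.integer(lm[[spp]]) else 0L)
    }
    dup_at <- integer(famrecon:::n_nodes(sp))
    tab <- table(rec$M[rec$event == "D"])
    dup_at[as.integer(names(tab))] <- as.integer(tab)
    origin <- sx$id_of[[origin_node(rec)]]
    for (v in seq_along(N)) {
      p <- sx$parent[v]
      if (is.na(p)) next
      if (v == origin) {
        expect_identical(unname(N[v]),
                         1L + dup_at[v] - unname(rec$losses_on_edge[v]))
      } else {
        expect_identical(unname(N[v] - N[p]),
                         dup_at[v] - unname(rec$losses_on_edge[v]))
      }
    }
  }
})

test_that("origin_node is the mapping of the gene-tree root", {
  gt <- parse_newick("(A_1,A_2)d;")
  expect_equal(origin_node(reconcile(gt, sp_abc, lm_auto(gt, sp_abc))), "A")
  gt2 <- parse_newick("(A_1,C_1)r;")
  expect_equal(origin_node(reconcile(gt2, sp_abc, lm_auto(gt2, sp_abc))), "R")
  # simulated: equals the logged origin unless basal losses mask it
  masked <- 0L; total <- 0L
  for (s in 1:40) {
    fam <- simulate_family(sp, sim_params(0.4, 0.3, seed = 9000 + s))
    if (fam$extinct) next
    rec <- reconcile(fam$gene_tree, sp, lm_auto(fam$gene_tree, sp))
    total <- total + 1L
    if (origin_node(rec) != "Chordata") masked <- masked + 1L
  }
  expect_gt(total - masked, 0)
})

test_that("orthogroups cut at duplication nodes and name by reference", {
  spt <- parse_newick("(Hsap:1,Mmus:1)Mam;")
  gt <- parse_newick("((Hsap_X1,Mmus_X1)a,(Hsap_X2,Mmus_X2)b)d;")
  og <- orthogroups(reconcile(gt, spt, lm_auto(gt, spt)),
                    reference_species = c("Hsap", "Mmus"))
  expect_setequal(names(og$groups), c("X1", "X2"))
  expect_setequal(og$groups$X1, c("Hsap_X1", "Mmus_X1"))

  # no duplication: one group
  gt0 <- parse_newick("(Hsap_X1,Mmus_X1)s;")
  og0 <- orthogroups(reconcile(gt0, spt, lm_auto(gt0, spt)),
                     reference_species = "Hsap")
  expect_length(og0$groups, 1)
  expect_equal(names(og0$groups), "X1")

  # unnamed groups when no reference member
  og1 <- orthogroups(reconcile(gt, spt, lm_auto(gt, spt)),
                     reference_species = character(0))
  expect_true(all(grepl("^unnamed-", names(og1$groups))))
})

test_that("cut_above restricts cutting to duplications at/above a node", {
  # species ((A,B)AB,C)R; duplication at AB (deep) and at A (shallow)
  gt <- parse_newick("((((A_p1,A_p2)dA,B_p)x,(A_q,B_q)y)dAB,C_r)r;")
  rec <- reconcile(gt, sp_abc, lm_auto(gt, sp_abc))
  # sanity: two duplications, one at AB and one at A
  labs <- famrecon:::node_labels(sp_abc)
  expect_setequal(labs[rec$M[rec$event == "D"]], c("AB", "A"))
  # cutting both D nodes leaves 5 components:
  # {A_p1}, {A_p2}, {B_p}, {A_q,B_q}, {C_r}
  og_all <- orthogroups(rec, reference_species = character(0))
  expect_length(og_all$groups, 5)
  # only the duplication at/above AB splits: {A_p1,A_p2,B_p}, {A_q,B_q}, {C_r}
  og_cut <- orthogroups(rec, reference_species = character(0),
                        cut_above = "AB")
  expect_length(og_cut$groups, 3)
  expect_equal(sort(unname(lengths(og_cut$groups))), c(1L, 2L, 3L))
})

test_that("presence_matrix marks species with at least one member", {
  spt <- parse_newick("(Hsap:1,Mmus:1)Mam;")
  gt <- parse_newick("((Hsap_X1,Mmus_X1)a,(Hsap_X2,Mmus_X2)b)d;")
  rec <- reconcile(gt, spt, lm_auto(gt, spt))
  og <- orthogroups(rec, reference_species = c("Hsap", "Mmus"))
  pm <- presence_matrix(og, c("Hsap", "Mmus", "Ggal"),
                        leaf_maps = list(rec$leaf_map))
  expect_true(all(pm[c("Hsap", "Mmus"), c("X1", "X2")]))
  expect_false(any(pm["Ggal", ]))
  # matrix equals a direct leaf count on simulated data
  fam <- simulate_family(sp, sim_params(0.5, 0.2, seed = 12))
  rec2 <- reconcile(fam$gene_tree, sp, lm_auto(fam$gene_tree, sp))
  og2 <- orthogroups(rec2)
  pm2 <- presence_matrix(og2, sp$tip.label, leaf_maps = list(rec2$leaf_map))
  have <- unique(unname(rec2$leaf_map))
  expect_setequal(rownames(pm2)[rowSums(pm2) > 0], have)
})

test_that("duplication_bursts localises forced duplications", {
  recs <- lapply(1:30, function(s) {
    fam <- simulate_family(
      sp, sim_params(0, 0,
                     overrides = list(Gnathostomata = c(dup = 4, loss = 0)),
                     seed = 600 + s))
    reconcile(fam$gene_tree, sp, lm_auto(fam$gene_tree, sp))
  })
  b <- duplication_bursts(recs)
  expect_true(sum(b$n_dup) > 0)
  expect_equal(sum(b$n_dup[b$node != "Gnathostomata"]), 0L)
  # no duplications anywhere -> all zero
  rec0 <- reconcile(simulate_family(sp, sim_params(0, 0, seed = 1))$gene_tree,
                    sp, lm_auto(simulate_family(
                      sp, sim_params(0, 0, seed = 1))$gene_tree, sp))
  expect_true(all(duplication_bursts(list(rec0))$n_dup == 0L))
  # per-node counts equal event-log counts on loss-free runs
  for (s in 1:20) {
    fam <- simulate_family(sp, sim_params(0.4, 0, seed = 700 + s))
    rec <- reconcile(fam$gene_tree, sp, lm_auto(fam$gene_tree, sp))
    b1 <- duplication_bursts(list(rec))
    logd <- fam$events[fam$events$event == "duplication", "species"]
    for (nd in b1$node) {
      expect_identical(b1$n_dup[b1$node == nd], sum(logd == nd))
    }
  }
})

test_that("aggregate_groups sums member families and preserves totals", {
  fams <- lapply(1:4, function(k)
    simulate_family(sp, sim_params(0.3, 0.1, seed = 800 + k),
                    family_id = paste0("fam", k)))
  recs <- lapply(fams, function(f)
    reconcile(f$gene_tree, sp, lm_auto(f$gene_tree, sp)))
  names(recs) <- paste0("fam", 1:4)
  tab <- complement_table(recs)
  gm <- c(fam1 = "L1", fam2 = "L1", fam3 = "L2", fam4 = "L2")
  agg <- aggregate_groups(tab, gm)
  expect_equal(unname(agg[, "L1"]), unname(tab[, "fam1"] + tab[, "fam2"]))
  expect_equal(rowSums(agg), rowSums(tab))
  # identity grouping
  expect_equal(unname(aggregate_groups(tab, stats::setNames(
    colnames(tab), colnames(tab)))), unname(tab))
  expect_error(aggregate_groups(tab, gm[-1]), "fam1")
})
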