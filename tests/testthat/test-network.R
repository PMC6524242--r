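test_that("pearson_edge matches hand values and the textbook oracle", {
  expect_equal(pearson_edge(c(1, 2, 3, 4), c(1, 2, 3, 4))$pcc, 1)
  expect_equal(pearson_edge(c(1, 2, 3, 4), c(1, 2, 3, 4))$p, 0)
  expect_equal(pearson_edge(c(1, 2, 3, 4), c(4, 3, 2, 1))$pcc, -1)

  x <- c(1, 2, 3, 4, 5, 6); y <- c(2, 1, 4, 3, 6, 5)
  got <- pearson_edge(x, y)
  orc <- oracle_pearson(x, y)
  expect_equal(got$pcc, orc$r, tolerance = 1e-12)
  expect_equal(got$p, orc$p, tolerance = 1e-12)
  # also agrees with stats::cor.test
  ct <- cor.test(x, y)
  expect_equal(got$pcc, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(got$p, ct$p.value, tolerance = 1e-12)

  # symmetry over random draws
  withr::with_seed(5, {
    for (i in 1:10) {
      a <- rnorm(8); b <- rnorm(8)
      expect_identical(pearson_edge(a, b), pearson_edge(b, a))
    }
  })
  expect_error(pearson_edge(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(pearson_edge(1:2, 1:2), "3 samples")
})

test_that("network edges match all-pairs brute-force enumeration", {
  withr::with_seed(11, {
    n_nodes <- 20
    vals_tc <- matrix(rlnorm(n_nodes * 6), nrow = n_nodes)
    vals_tam <- matrix(rlnorm(n_nodes * 6), nrow = n_nodes)
    rownames(vals_tc) <- rownames(vals_tam) <- sprintf("G%03d", 1:n_nodes)
    exp <- toy_experiment(vals_tc, rep("Ep", 6), vals_tam)
    genes <- sprintf("G%03d", 1:10)
    net <- suppressMessages(build_network(
      exp, list(TC = genes, TAM = genes), animals = sprintf("A%02d", 1:6)))

    # brute force over all 190 unordered node pairs
    dat <- rbind(vals_tc[genes, ], vals_tam[genes, ])
    ids <- c(paste0(genes, "|TC"), paste0(genes, "|TAM"))
    expected <- character()
    for (i in seq_along(ids)) for (j in seq_len(i - 1)) {
      o <- oracle_pearson(dat[i, ], dat[j, ])
      if (abs(o$r) > 0.95 && o$p < 0.05) {
        expected <- c(expected, paste(sort(c(ids[i], ids[j])), collapse = "~"))
      }
    }
    got <- paste(pmin(net$edges$node_a, net$edges$node_b),
                 pmax(net$edges$node_a, net$edges$node_b), sep = "~")
    expect_setequal(got, expected)
  })
})

test_that("edge thresholds are strict and collinear pairs are detected", {
  # y built by Gram-Schmidt so cor(x, y) = 0.95 up to rounding
  x <- c(1, 2, 3, 4, 5, 6)
  cx <- x - mean(x)
  v <- c(1, 0, 0, 0, 0, -1)
  u <- v - sum(v * cx) / sum(cx^2) * cx
  y <- 0.95 * cx / sqrt(sum(cx^2)) + sqrt(1 - 0.95^2) * u / sqrt(sum(u^2))
  r_val <- cor(x, y)
  expect_equal(r_val, 0.95, tolerance = 1e-12)
  vals <- rbind(GX = x, GY = y + 10, GZ = 2 * x + 1, GW = c(9, 1, 7, 3, 8, 2))
  exp <- toy_experiment(vals, rep("Ep", 6))
  # read the network's own value for the boundary pair, then use it as the
  # threshold: the strict inequality must exclude exactly that pair
  permissive <- suppressMessages(build_network(
    exp, list(TC = c("GX", "GY", "GZ", "GW"), TAM = character()),
    animals = sprintf("A%02d", 1:6),
    cfg = analysis_config(edge_abs_pcc_threshold = 0.5)))
  r_val <- permissive$edges$pcc[permissive$edges$node_a == "GX|TC" &
                                  permissive$edges$node_b == "GY|TC"]
  expect_equal(r_val, 0.95, tolerance = 1e-12)
  net <- suppressMessages(build_network(
    exp, list(TC = c("GX", "GY", "GZ", "GW"), TAM = character()),
    animals = sprintf("A%02d", 1:6),
    cfg = analysis_config(edge_abs_pcc_threshold = r_val)))
  got <- paste(pmin(net$edges$node_a, net$edges$node_b),
               pmax(net$edges$node_a, net$edges$node_b))
  # GX~GY sits exactly at the threshold: excluded by strict inequality;
  # only the exactly collinear pair GX~GZ passes
  expect_equal(got, "GX|TC GZ|TC")
  expect_equal(net$topology$n_nodes, 2)

  # nudging the threshold below r_val admits the boundary pair
  net2 <- suppressMessages(build_network(
    exp, list(TC = c("GX", "GY", "GZ", "GW"), TAM = character()),
    animals = sprintf("A%02d", 1:6),
    cfg = analysis_config(edge_abs_pcc_threshold = r_val - 1e-9)))
  expect_equal(nrow(net2$edges), 3)  # GX~GY, GX~GZ, GY~GZ

  expect_error(build_network(exp, list(TC = "GX", TAM = character()),
                             animals = sprintf("A%02d", 1:2)),
               "3 paired samples")
})

test_that("edge sets are invariant to gene ordering", {
  withr::with_seed(3, {
    vals <- matrix(rlnorm(8 * 6), nrow = 8,
                   dimnames = list(sprintf("G%03d", 1:8), NULL))
    exp <- toy_experiment(vals, rep("Ep", 6))
    g <- sprintf("G%03d", 1:8)
    n1 <- suppressMessages(build_network(exp, list(TC = g, TAM = g),
                                         sprintf("A%02d", 1:6)))
    n2 <- suppressMessages(build_network(exp, list(TC = rev(g), TAM = sample(g)),
                                         sprintf("A%02d", 1:6)))
    key <- function(n) sort(paste(pmin(n$edges$node_a, n$edges$node_b),
                                  pmax(n$edges$node_a, n$edges$node_b)))
    expect_identical(key(n1), key(n2))
  })
})

test_that("sensitive and perturbation networks follow the 6-vs-single-rebound design", {
  sim <- simulate_mouse_experiment(mouse_truth(n_genes = 40,
                                               n_deg_per_compartment = 5),
                                   seed = 6)
  norm <- suppressMessages(vehicle_normalize(sim$experiment))
  nodes <- list(TC = sprintf("G%04d", 1:12), TAM = sprintf("G%04d", 1:12))
  nets <- suppressMessages(build_sensitive_and_perturbation_networks(norm, nodes))
  expect_length(nets$perturbations, 4)
  expect_equal(length(nets$sensitive$animals), 6)
  for (p in nets$perturbations) {
    expect_equal(length(p$animals), 7)
    expect_identical(rownames(p$data), rownames(nets$sensitive$data))
  }
})

test_that("adding an on-line point preserves perfect correlation", {
  # collinear endpoint data; the rebound sample lies exactly on the line
  x <- c(1, 2, 3, 4, 5, 6, 7)
  vals <- rbind(GX = x, GY = 3 * x + 2)
  groups <- c(rep("Ep", 6), "Reb")
  vals2 <- rbind(GX = c(1, x), GY = c(5, 3 * x + 2))
  exp <- toy_experiment(vals2, c("Veh", groups))
  nets <- suppressMessages(build_sensitive_and_perturbation_networks(
    exp, list(TC = c("GX", "GY"), TAM = character())))
  e_sens <- nets$sensitive$edges
  e_pert <- nets$perturbations[[1]]$edges
  expect_equal(nrow(e_sens), 1)
  expect_equal(nrow(e_pert), 1)
  expect_equal(e_sens$pcc, 1, tolerance = 1e-12)
  expect_equal(e_pert$pcc, 1, tolerance = 1e-12)
})

test_that("topology metrics match hand computation and an igraph oracle", {
  # path a-b-c-d: diameter 3, avg neighbors 1.5
  path_edges <- tibble::tibble(node_a = c("a", "b", "c"),
                               node_b = c("b", "c", "d"))
  t_path <- topology_metrics(path_edges)
  expect_equal(t_path$diameter, 3)
  expect_equal(t_path$avg_neighbors, 1.5)
  expect_equal(t_path$n_nodes, 4L)

  # star on 4 nodes: Freeman centralization 1
  star_edges <- tibble::tibble(node_a = "hub", node_b = c("x", "y", "z"))
  expect_equal(topology_metrics(star_edges)$centralization, 1)

  # random graph vs igraph's own metrics
  withr::with_seed(8, {
    g <- igraph::sample_gnp(20, 0.15)
    el <- igraph::as_edgelist(g)
    edges <- tibble::tibble(node_a = as.character(el[, 1]),
                            node_b = as.character(el[, 2]))
    t_got <- topology_metrics(edges)
    comps <- igraph::components(g)
    sub <- igraph::induced_subgraph(
      g, which(comps$membership == which.max(comps$csize)))
    expect_equal(t_got$diameter, igraph::diameter(sub))
    non_iso <- sum(igraph::degree(g) > 0)
    expect_equal(t_got$n_nodes, non_iso)
    expect_equal(t_got$avg_neighbors, 2 * igraph::ecount(g) / non_iso)
    deg <- igraph::degree(g)[igraph::degree(g) > 0]
    expect_equal(t_got$centralization,
                 sum(max(deg) - deg) / ((non_iso - 1) * (non_iso - 2)))
  })

  # degenerate graphs return defined zeros
  t0 <- topology_metrics(tibble::tibble(node_a = character(),
                                        node_b = character()))
  expect_equal(t0$diameter, 0)
  expect_equal(t0$centralization, 0)
})
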