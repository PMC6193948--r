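ortho_table <- function(occ = c(A = 0.7, B = NA, C = NA, D = NA, E = NA,
                                F = 0.7),
                        ratio = 0.14, id = "test-ortho") {
  occupancy_table(id, ratio,
                  chain = names(occ),
                  conformation = c("closed", "open", "open", "open",
                                   "open", "closed"),
                  partner = c("D", "E", "F", "A", "B", "C"),
                  occupancy = unname(occ))
}

test_that("site classification follows own + partner conformation", {
  cls <- classify_sites(ortho_table())
  expect_equal(cls[["A"]], "closed")
  expect_equal(cls[["F"]], "closed")
  expect_equal(cls[["D"]], "open_in_closed_open_dimer")
  expect_equal(cls[["C"]], "open_in_closed_open_dimer")
  expect_equal(cls[["B"]], "open_in_open_open_dimer")
  expect_equal(cls[["E"]], "open_in_open_open_dimer")
  # hexagonal, symmetry-expanded: A closed with partner D; B paired to B'
  hex <- occupancy_table("test-hex", 0.57,
                         chain = c("A", "D", "B", "A'", "D'", "B'"),
                         conformation = c("closed", "open", "open",
                                          "closed", "open", "open"),
                         partner = c("D", "A", "B'", "D'", "A'", "B"),
                         occupancy = c(0.8, 0.5, 0.4, 0.8, 0.5, 0.4))
  clh <- classify_sites(hex)
  expect_equal(clh[["D"]], "open_in_closed_open_dimer")
  expect_equal(clh[["B"]], "open_in_open_open_dimer")
  expect_equal(clh[["B'"]], "open_in_open_open_dimer")
  # all-open hexamer
  allopen <- occupancy_table("all-open", 1,
                             chain = LETTERS[1:6],
                             conformation = rep("open", 6),
                             partner = c("D", "E", "F", "A", "B", "C"),
                             occupancy = rep(0.5, 6))
  expect_true(all(classify_sites(allopen) == "open_in_open_open_dimer"))
  # broken dimer map is refused
  expect_error(occupancy_table("bad", 1, chain = c("A", "B"),
                               conformation = c("open", "open"),
                               partner = c("A", "A"),
                               occupancy = c(0.5, 0.5)),
               "pair")
})

test_that("class mean occupancy averages members, absent ligand as zero", {
  t <- ortho_table(c(A = 0.7, B = NA, C = 0.6, D = 0.2, E = NA, F = 0.7))
  expect_equal(class_mean_occupancy(t, "closed"), 0.7)
  expect_equal(class_mean_occupancy(t, "open_in_closed_open_dimer"), 0.4)
  expect_equal(class_mean_occupancy(t, "open_in_open_open_dimer"), 0)
  allopen <- occupancy_table("all-open", 1, chain = LETTERS[1:6],
                             conformation = rep("open", 6),
                             partner = c("D", "E", "F", "A", "B", "C"),
                             occupancy = rep(0.5, 6))
  expect_true(is.na(class_mean_occupancy(allopen, "closed")))
})

test_that("packaged occupancy series reproduce the published class means", {
  fx <- pnp_fa_occupancy()
  expect_length(fx, 5)
  wt2 <- fx[["WT-6(P/S)-2FA"]]
  expect_equal(class_mean_occupancy(wt2, "closed"), 0.7)
  expect_equal(class_mean_occupancy(wt2, "open_in_closed_open_dimer"), 0)
  dm4 <- fx[["DM-6(P/S)-4FA"]]
  expect_equal(class_mean_occupancy(dm4, "closed"), 0.6)
  expect_equal(class_mean_occupancy(dm4, "open_in_closed_open_dimer"), 0.6)
  expect_equal(class_mean_occupancy(dm4, "open_in_open_open_dimer"), 0)
})

test_that("filling order: wild type closed-first, double mutant reversed", {
  fx <- pnp_fa_occupancy()
  wt <- filling_order(fx[grepl("^WT", names(fx))], occ_threshold = 0.4)
  expect_equal(wt$site_class[1], "closed")
  expect_equal(wt$first_ratio[1], 0.14)
  expect_true(all(wt$first_ratio[2:3] == 0.57))

  dm <- filling_order(fx[grepl("^DM", names(fx))], occ_threshold = 0.4)
  expect_equal(dm$site_class,
               c("open_in_closed_open_dimer", "closed",
                 "open_in_open_open_dimer"))
  expect_equal(dm$first_ratio, c(0.4, 0.6, 1.2))
})

test_that("filling order is invariant to topology-preserving relabeling", {
  fx <- pnp_fa_occupancy()
  dm <- fx[grepl("^DM", names(fx))]
  relabel <- function(t) {
    map <- c(A = "F", F = "A", B = "E", E = "B", C = "D", D = "C",
             "A'" = "A'", "B'" = "B'", "D'" = "D'")
    occupancy_table(attr(t, "structure_id"), attr(t, "molar_ratio"),
                    chain = unname(map[t$chain]),
                    conformation = t$conformation,
                    partner = unname(map[t$partner]),
                    occupancy = t$occupancy)
  }
  expect_equal(filling_order(lapply(dm, relabel)), filling_order(dm))
})

test_that("all-unoccupied series yields 'never' for every class", {
  t <- ortho_table(c(A = NA, B = NA, C = NA, D = NA, E = NA, F = NA))
  fo <- filling_order(list(t), occ_threshold = 0.4)
  expect_true(all(is.na(fo$first_ratio)))
  expect_error(filling_order(list()), "empty")
  expect_error(filling_order(list(t), occ_threshold = 1.5), "0, 1")
})

test_that("order inference agrees with the titration generator's truth", {
  ratios <- c(0.2, 0.5, 1, 2, 4, 8)
  # closed sites bind tightest, open-open weakest
  t_closed <- simulate_titration(50, 0.2, ratios, 0.5)
  t_open_co <- simulate_titration(5, 0.2, ratios, 0.5)
  t_open_oo <- simulate_titration(0.5, 0.2, ratios, 0.5)
  series <- titration_to_occupancy(t_closed, t_open_co, t_open_oo)
  fo <- filling_order(series, occ_threshold = 0.4)
  expect_equal(fo$site_class,
               c("closed", "open_in_closed_open_dimer",
                 "open_in_open_open_dimer"))
  expect_true(all(diff(fo$first_ratio) > 0))
})
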