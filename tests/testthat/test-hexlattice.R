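test_that("every site has exactly 6 distinct neighbors, also under wrap-around", {
  lat <- hex_lattice(10, 10, 1)
  for (s in c(1L, 37L, 100L)) {
    nb <- hex_neighbors(lat, s)
    expect_length(nb, 6L)
    expect_length(unique(nb), 6L)
    expect_false(s %in% nb)
  }
  # smallest admissible lattice: wrap-around must still give 6 distinct sites
  lat3 <- hex_lattice(3, 3, 1)
  corner <- site_index(lat3, 0, 0)
  nb <- hex_neighbors(lat3, corner)
  expect_length(unique(nb), 6L)
})

test_that("adjacency is symmetric and irreflexive (brute force over all pairs)", {
  for (dims in list(c(5, 5), c(4, 7))) {
    lat <- hex_lattice(dims[1], dims[2], 1)
    ns <- dims[1] * dims[2]
    A <- matrix(0L, ns, ns)
    for (s in seq_len(ns)) A[s, hex_neighbors(lat, s)] <- 1L
    expect_identical(A, t(A))
    expect_true(all(diag(A) == 0L))
    expect_true(all(rowSums(A) == 6L))
  }
})

test_that("invalid sites and sub-3 lattices are rejected", {
  lat <- hex_lattice(5, 5, 1)
  expect_error(hex_neighbors(lat, 0), "out of range")
  expect_error(hex_neighbors(lat, 26), "out of range")
  expect_error(hex_neighbors(hex_lattice(2, 5, 1), 1), "width >= 3")
})

test_that("site index <-> axial coordinate conversion round-trips", {
  lat <- hex_lattice(7, 4, 1)
  s <- seq_len(28)
  xy <- site_coords(lat, s)
  expect_identical(site_index(lat, xy$col, xy$row), as.integer(s))
})

test_that("initialization seeds species equally at the requested occupancy", {
  lat <- initialize_lattice(60, 60, 4, 0.10, seed = 1)
  counts <- count_abundances(lat)$counts
  expect_identical(counts, rep(90L, 4))
  expect_identical(sum(lat$occupancy > 0), 360L)

  # indivisible total: counts differ by at most one cell
  lat2 <- initialize_lattice(10, 10, 3, 0.50, seed = 1)
  c2 <- count_abundances(lat2)$counts
  expect_identical(sum(c2), 50L)
  expect_lte(max(c2) - min(c2), 1L)

  # full occupancy, single species, 2x2 lattice allowed for state construction
  lat3 <- initialize_lattice(2, 2, 1, 1.0, seed = 1)
  expect_identical(lat3$occupancy, rep(1L, 4))
})

test_that("initialization is deterministic given a seed and leaves the caller's RNG alone", {
  a <- initialize_lattice(20, 20, 4, 0.3, seed = 99)
  b <- initialize_lattice(20, 20, 4, 0.3, seed = 99)
  expect_identical(a$occupancy, b$occupancy)

  set.seed(7); before <- runif(1)
  set.seed(7); invisible(initialize_lattice(10, 10, 2, 0.5, seed = 1))
  expect_identical(runif(1), before)
})

test_that("abundance counting matches construction and respects capacity", {
  empty <- hex_lattice(6, 6, 4)
  expect_identical(count_abundances(empty)$counts, rep(0L, 4))

  lat <- single_species_lattice(20, 20, 200)
  lat$occupancy[201:250] <- 0L  # no-op: already empty
  expect_identical(count_abundances(lat)$counts, 200L)

  expect_error(abundance_vector(c(300, 200), total_sites = 400), "exceeds")
})

test_that("snapshot TSV round-trips exactly, including empty trailing rows", {
  lat <- initialize_lattice(12, 9, 4, 0.4, seed = 3)
  lat$occupancy[lat$occupancy > 0 & seq_along(lat$occupancy) > 80] <- 0L
  path <- withr::local_tempfile(fileext = ".tsv")
  write_snapshot(lat, path)
  back <- read_snapshot(path)
  expect_identical(back$occupancy, lat$occupancy)
  expect_identical(back$width, lat$width)
  expect_identical(back$height, lat$height)
  expect_identical(back$n_species, lat$n_species)
  expect_match(readLines(path)[4], "^col\trow\tspecies_id$")
})
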