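test_that("edge-list construction builds the symmetric binary matrix", {
  w <- build_rook_from_edges(cbind(c("A", "B"), c("B", "C")),
                             region_set(c("A", "B", "C")))
  expect_equal(unname(w$W0),
               matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3, 3))
  expect_false(w$standardized)
  expect_symmetric_zero_diag(w)

  # empty edge list: all rows zero, flagged as isolates, refused downstream
  w0 <- build_rook_from_edges(matrix(character(0), ncol = 2),
                              region_set(c("A", "B")))
  expect_equal(isolates(w0), c("A", "B"))
  expect_error(row_standardize(w0), "isolated")

  expect_error(build_rook_from_edges(cbind("A", "Z"),
                                     region_set(c("A", "B"))), "unknown")
  expect_error(build_rook_from_edges(cbind("A", "A"),
                                     region_set(c("A", "B"))), "self-pair")
})

test_that("the packaged 31-province fixture is a valid rook structure", {
  w <- china_provinces(patch_hainan = FALSE, standardize = FALSE)
  expect_equal(w$regions$n, 31L)
  expect_symmetric_zero_diag(w)
  expect_true(all(w$W0 %in% c(0, 1)))
  expect_equal(isolates(w), "Hainan")

  patched <- china_provinces()
  expect_true(patched$standardized)
  expect_equal(max(abs(rowSums(patched$W) - 1)), 0, tolerance = 1e-12)
  gd <- which(region_ids(patched) == "Guangdong")
  hn <- which(region_ids(patched) == "Hainan")
  expect_equal(patched$W0[hn, gd], 1)
})

test_that("island patching adds symmetric links and reports leftovers", {
  w <- build_rook_from_edges(cbind("A", "B"),
                             region_set(c("A", "B", "D")))
  p <- patch_islands(w, cbind("D", "A"))
  expect_equal(p$W0["D", "A"], 1)
  expect_equal(p$W0["A", "D"], 1)

  # empty patch list on a connected matrix is the identity
  tri <- build_rook_from_edges(rbind(c("A", "B"), c("B", "C"),
                                     c("A", "C")),
                               region_set(c("A", "B", "C")))
  expect_identical(patch_islands(tri, NULL)$W0, tri$W0)

  # naming a non-isolate as isolate: applied anyway, with a warning
  expect_warning(p2 <- patch_islands(tri, cbind("A", "B")),
                 "already has")
  expect_equal(p2$W0["A", "B"], 1)

  # patch that leaves an isolate errors with the offending id
  w2 <- build_rook_from_edges(cbind("A", "B"),
                              region_set(c("A", "B", "D", "E")))
  expect_error(patch_islands(w2, cbind("D", "A")), "E")
})

test_that("row standardization divides by degree and flags isolates", {
  path <- build_rook_from_edges(rbind(c("A", "B"), c("B", "C")),
                                region_set(c("A", "B", "C")))
  s <- row_standardize(path)
  expect_equal(unname(s$W["B", ]), c(0.5, 0, 0.5))
  expect_equal(rowSums(s$W), setNames(rep(1, 3), c("A", "B", "C")),
               tolerance = 1e-12)
  # symmetric W0 with unequal degrees gives asymmetric W
  expect_false(isTRUE(all.equal(s$W, t(s$W))))
  # regular graph: W = W0 / k
  ring <- build_rook_from_edges(rbind(c("A", "B"), c("B", "C"),
                                      c("C", "D"), c("D", "A")),
                                region_set(c("A", "B", "C", "D")))
  sr <- row_standardize(ring)
  expect_equal(sr$W, ring$W0 / 2)
})

test_that("polygon-derived rook adjacency requires shared edges, not corners", {
  sq <- function(x0, y0) cbind(c(x0, x0 + 1, x0 + 1, x0, x0),
                               c(y0, y0, y0 + 1, y0 + 1, y0))
  # shared full edge -> adjacent
  w <- build_rook_from_polygons(list(a = sq(0, 0), b = sq(1, 0)))
  expect_equal(w$W0["a", "b"], 1)
  # corner contact only -> not adjacent (rook, not queen)
  w2 <- build_rook_from_polygons(list(a = sq(0, 0), b = sq(1, 1)))
  expect_equal(w2$W0["a", "b"], 0)

  grid_polys <- function(r, c) {
    g <- list()
    for (i in seq_len(r)) for (j in seq_len(c)) {
      g[[paste0(i, "_", j)]] <- sq(j - 1, i - 1)
    }
    g
  }
  # 2x2 grid of unit squares: exactly 4 rook adjacencies
  w3 <- build_rook_from_polygons(grid_polys(2, 2))
  expect_equal(sum(w3$W0) / 2, 4)
  # r x c grid: r(c-1) + c(r-1) adjacencies
  w4 <- build_rook_from_polygons(grid_polys(3, 4))
  expect_equal(sum(w4$W0) / 2, 3 * 3 + 4 * 2)
  expect_error(build_rook_from_polygons(list(a = cbind(0, 0))), "invalid")
})

test_that("GAL round-trip is exact and parse errors carry line numbers", {
  tri <- build_rook_from_edges(rbind(c("A", "B"), c("B", "C"),
                                     c("A", "C")),
                               region_set(c("A", "B", "C")))
  f <- tempfile(fileext = ".gal")
  write_gal(tri, f)
  back <- read_gal(f)
  expect_identical(back$W0, tri$W0)
  expect_identical(region_ids(back), region_ids(tri))

  # 31-province fixture round-trips bit-exactly too
  cn <- china_provinces(standardize = FALSE)
  f2 <- tempfile(fileext = ".gal")
  write_gal(cn, f2)
  expect_identical(read_gal(f2)$W0, cn$W0)

  # truncated file: declared n = 3 but two records
  writeLines(c("3", "A 1", "B", "B 1", "A"), f)
  expect_error(read_gal(f), "line")

  # asymmetric neighbour lists rejected unless symmetrized
  writeLines(c("2", "A 1", "B", "B 0"), f)
  expect_error(read_gal(f), "asymmetric")
  fixed <- read_gal(f, symmetrize = TRUE)
  union <- build_rook_from_edges(cbind("A", "B"), region_set(c("A", "B")))
  expect_identical(fixed$W0, union$W0)
})

test_that("GeoJSON polygons feed the rook builder", {
  gj <- list(type = "FeatureCollection", features = list(
    list(type = "Feature", properties = list(name = "a"),
         geometry = list(type = "Polygon", coordinates = list(
           list(list(0, 0), list(1, 0), list(1, 1), list(0, 1),
                list(0, 0))))),
    list(type = "Feature", properties = list(name = "b"),
         geometry = list(type = "Polygon", coordinates = list(
           list(list(1, 0), list(2, 0), list(2, 1), list(1, 1),
                list(1, 0))))),
    list(type = "Feature", properties = list(name = "c"),
         geometry = list(type = "Polygon", coordinates = list(
           list(list(2, 1), list(3, 1), list(3, 2), list(2, 2),
                list(2, 1)))))
  ))
  f <- tempfile(fileext = ".geojson")
  jsonlite::write_json(gj, f, auto_unbox = TRUE)
  polys <- read_geojson_polygons(f, id_property = "name")
  expect_named(polys, c("a", "b", "c"))
  w <- build_rook_from_polygons(polys)
  expect_equal(w$W0["a", "b"], 1)   # shared edge
  expect_equal(w$W0["b", "c"], 0)   # corner contact only
  expect_error(read_geojson_polygons(f, id_property = "missing"),
               "property")
})

test_that("edge CSV round-trips and centroid patch suggestions work", {
  w <- china_provinces(patch_hainan = FALSE, standardize = FALSE)
  f <- tempfile(fileext = ".csv")
  write_edge_csv(w, f)
  back <- read_edge_csv(f, w$regions)
  expect_identical(back$W0, w$W0)

  sq <- build_rook_from_edges(cbind("A", "B"),
                              region_set(c("A", "B", "D")))
  cents <- rbind(A = c(0, 0), B = c(1, 0), D = c(0.2, 1))
  sug <- suggest_island_patches(sq, cents)
  expect_equal(sug$isolate, "D")
  expect_equal(sug$candidate, "A")
})
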