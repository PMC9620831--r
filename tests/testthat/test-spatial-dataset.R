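test_that("CSV write/read round-trips every field, joining on cell id", {
  ds <- make_toy_dataset(n = 2, g = 3, seed = 3)
  dir <- withr::local_tempdir()
  write_spatial_dataset(ds, dir, format = "csv")
  ds2 <- read_spatial_dataset(file.path(dir, "expression.csv"),
                              file.path(dir, "coordinates.csv"),
                              file.path(dir, "labels.csv"), format = "csv")
  expect_equal(ds2$expression, ds$expression)
  expect_equal(ds2$coordinates, ds$coordinates)
  expect_equal(ds2$labels, ds$labels)

  # shuffled coordinate/label rows must join back by id, not by position
  coords <- read.csv(file.path(dir, "coordinates.csv"))
  write.csv(coords[rev(seq_len(nrow(coords))), ],
            file.path(dir, "coordinates.csv"), row.names = FALSE, quote = FALSE)
  ds3 <- read_spatial_dataset(file.path(dir, "expression.csv"),
                              file.path(dir, "coordinates.csv"),
                              file.path(dir, "labels.csv"), format = "csv")
  expect_equal(ds3$coordinates, ds$coordinates)
})

test_that("MTX input (with explicit zeros) matches an independent triplet expansion", {
  dir <- withr::local_tempdir()
  # hand-written MatrixMarket file: 3 cells x 4 genes, one explicit zero
  mtx <- c("%%MatrixMarket matrix coordinate real general",
           "3 4 5",
           "1 1 2.5", "2 3 1.0", "3 4 7.0", "1 4 0.0", "3 1 3.0")
  writeLines(mtx, file.path(dir, "expr.mtx"))
  writeLines(paste0("g", 1:4), file.path(dir, "genes.txt"))
  writeLines(paste0("c", 1:3), file.path(dir, "cells.txt"))
  write.csv(data.frame(cell_id = paste0("c", 1:3), x = 1:3, y = 0),
            file.path(dir, "coords.csv"), row.names = FALSE, quote = FALSE)
  write.csv(data.frame(cell_id = paste0("c", 1:3), cell_type = c("A", "B", "A")),
            file.path(dir, "labels.csv"), row.names = FALSE, quote = FALSE)

  ds <- read_spatial_dataset(file.path(dir, "expr.mtx"),
                             file.path(dir, "coords.csv"),
                             file.path(dir, "labels.csv"),
                             format = "mtx",
                             genes_path = file.path(dir, "genes.txt"),
                             cells_path = file.path(dir, "cells.txt"))
  # oracle: expand the triplets into a dense matrix by hand
  dense <- matrix(0, 3, 4, dimnames = list(paste0("c", 1:3), paste0("g", 1:4)))
  for (line in mtx[-(1:2)]) {
    v <- as.numeric(strsplit(line, " ")[[1]])
    dense[v[1], v[2]] <- v[3]
  }
  expect_equal(ds$expression, dense)

  # write -> load is idempotent for the MTX path as well
  dir2 <- withr::local_tempdir()
  write_spatial_dataset(ds, dir2, format = "mtx")
  ds2 <- read_spatial_dataset(file.path(dir2, "expression.mtx"),
                              file.path(dir2, "coordinates.csv"),
                              file.path(dir2, "labels.csv"), format = "mtx",
                              genes_path = file.path(dir2, "genes.txt"),
                              cells_path = file.path(dir2, "cells.txt"))
  expect_equal(ds2$expression, ds$expression)
  expect_equal(ds2$labels, ds$labels)
})

test_that("inconsistent or invalid inputs fail with informative errors", {
  ds <- make_toy_dataset(n = 4, g = 3, seed = 5)
  dir <- withr::local_tempdir()
  write_spatial_dataset(ds, dir, format = "csv")
  labs <- read.csv(file.path(dir, "labels.csv"))
  labs$cell_id[2] <- "rogue_cell"
  write.csv(labs, file.path(dir, "labels.csv"), row.names = FALSE, quote = FALSE)
  expect_error(
    read_spatial_dataset(file.path(dir, "expression.csv"),
                         file.path(dir, "coordinates.csv"),
                         file.path(dir, "labels.csv")),
    "rogue_cell")

  expect_error(spatial_dataset(matrix(c(-1, 2, 3, 4), 2, 2),
                               cbind(1:2, 1:2), c("A", "B")),
               "negative")
  expect_error(spatial_dataset(matrix(1, 2, 2), cbind(c(1, NA), 1:2),
                               c("A", "B")),
               "finite")
  m <- matrix(1, 2, 2, dimnames = list(c("c1", "c1"), c("g1", "g2")))
  expect_error(spatial_dataset(m, cbind(1:2, 1:2), c("A", "B")), "unique")
})

test_that("published real-dataset shapes are accepted", {
  # imaging-based shape: 523 cells x 10000 genes, 12 cell types, via MTX
  dir <- withr::local_tempdir()
  set.seed(9)
  expr <- Matrix::rsparsematrix(523, 10000, density = 0.001,
                                rand.x = function(n) rpois(n, 3) + 1)
  Matrix::writeMM(expr, file.path(dir, "expr.mtx"))
  writeLines(paste0("g", 1:10000), file.path(dir, "genes.txt"))
  writeLines(paste0("c", 1:523), file.path(dir, "cells.txt"))
  write.csv(data.frame(cell_id = paste0("c", 1:523),
                       x = runif(523), y = runif(523)),
            file.path(dir, "coords.csv"), row.names = FALSE, quote = FALSE)
  types <- paste0("T", 1:12)
  write.csv(data.frame(cell_id = paste0("c", 1:523),
                       cell_type = rep_len(types, 523)),
            file.path(dir, "labels.csv"), row.names = FALSE, quote = FALSE)
  ds <- read_spatial_dataset(file.path(dir, "expr.mtx"),
                             file.path(dir, "coords.csv"),
                             file.path(dir, "labels.csv"), format = "mtx",
                             genes_path = file.path(dir, "genes.txt"),
                             cells_path = file.path(dir, "cells.txt"))
  expect_equal(dim(ds$expression), c(523, 10000))
  expect_equal(nlevels(ds$labels), 12)

  # barcoding-based shape: 4489 spots x 10806 genes, 9 cell types, in memory
  expr2 <- Matrix::rsparsematrix(4489, 10806, density = 2e-4,
                                 rand.x = function(n) rpois(n, 2) + 1)
  rownames(expr2) <- paste0("s", 1:4489)
  colnames(expr2) <- paste0("g", 1:10806)
  ds2 <- spatial_dataset(expr2, cbind(runif(4489), runif(4489)),
                         rep_len(paste0("T", 1:9), 4489))
  expect_equal(dim(ds2$expression), c(4489, 10806))
  expect_equal(nlevels(ds2$labels), 9)
})
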