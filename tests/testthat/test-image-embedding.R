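make_category_fixture <- function() {
  # genes in a 2-sample feature space: two tight, well-separated clusters
  # plus a midpoint cluster so t = 3 (>= 2 discriminant axes)
  set.seed(77)
  a <- cbind(rnorm(10, 0, 0.05), rnorm(10, 0, 0.05))
  b <- cbind(rnorm(10, 4, 0.05), rnorm(10, 1, 0.05))
  mid <- cbind(rnorm(4, 2, 0.05), rnorm(4, 0.5, 0.05))
  Z <- rbind(a, mid, b)
  m <- nrow(Z)
  v <- Z
  dimnames(v) <- list(sprintf("g%02d", 1:m), c("s1", "s2"))
  em <- expression_set(v, c(s1 = "A", s2 = "B"), normalized = FALSE)
  cats <- data.frame(gene_id = rownames(v), distance = c(
    rep(0.1, 10), rep(0.5, 4), rep(0.9, 10)),
    category = c(rep(1L, 10), rep(2L, 4), rep(3L, 10)))
  class(cats) <- c("category_assignment", "data.frame")
  attr(cats, "t") <- 3L
  list(em = em, cats = cats, a = a, b = b)
}

test_that("leading LDA axis matches the closed-form two-class discriminant", {
  fx <- make_category_fixture()
  coords <- lda_project_genes(fx$em, fx$cats)
  expect_equal(nrow(coords), nrow(fx$em$values))
  expect_true(all(is.finite(coords$x)))
  expect_true(all(is.finite(coords$y)))

  # hand-coded two-class discriminant Sw^-1 (mu_a - mu_b) for the two
  # extreme clusters
  mu_a <- colMeans(fx$a); mu_b <- colMeans(fx$b)
  Sw <- crossprod(sweep(fx$a, 2, mu_a)) + crossprod(sweep(fx$b, 2, mu_b))
  w <- solve(Sw, mu_b - mu_a)

  # recover the fitted leading axis by regressing coordinates on features
  Z <- fx$em$values
  axis1 <- qr.solve(cbind(1, Z), coords$x)[2:3]
  cosine <- sum(axis1 * w) / sqrt(sum(axis1^2) * sum(w^2))
  expect_gt(abs(cosine), 0.99)

  # identical genes land on identical coordinates
  v <- fx$em$values
  v[2, ] <- v[1, ]
  em2 <- expression_set(v, fx$em$labels, normalized = FALSE)
  coords2 <- lda_project_genes(em2, fx$cats)
  expect_equal(unlist(coords2[1, c("x", "y")]),
               unlist(coords2[2, c("x", "y")]), tolerance = 1e-9)

  # sign convention: top-category centroid in the first quadrant
  top <- coords[fx$cats$category == 3L, ]
  expect_gte(mean(top$x), 0)
  expect_gte(mean(top$y), 0)
})

test_that("LDA embedding validates its preconditions", {
  fx <- make_category_fixture()
  cats2 <- fx$cats
  attr(cats2, "t") <- 2L
  cats2$category <- pmin(cats2$category, 2L)
  expect_error(lda_project_genes(fx$em, cats2), "dimensionality")

  lonely <- fx$cats
  lonely$category[11:14] <- c(2L, 3L, 3L, 3L)  # category 2 left with 1 gene
  expect_error(lda_project_genes(fx$em, lonely), "scatter-estimation")
})

test_that("minimum enclosing rectangle beats the axis-aligned box", {
  # diamond: area 2 at 45 degrees vs axis-aligned area 4
  diamond <- data.frame(x = c(0, 1, 2, 1), y = c(1, 0, 1, 2))
  r <- minimum_enclosing_rectangle(diamond)
  expect_equal(r$area, 2.0, tolerance = 1e-9)
  expect_equal(r$angle, pi / 4, tolerance = 1e-9)
  expect_equal(r$width, sqrt(2), tolerance = 1e-9)
  expect_equal(r$height, sqrt(2), tolerance = 1e-9)

  # axis-aligned unit square stays put
  sq <- data.frame(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1))
  rs <- minimum_enclosing_rectangle(sq)
  expect_equal(rs$area, 1.0, tolerance = 1e-12)
  expect_equal(rs$angle, 0)

  # degenerate inputs
  pt <- minimum_enclosing_rectangle(data.frame(x = 3, y = 4))
  expect_equal(pt$area, 0)
  seg <- minimum_enclosing_rectangle(data.frame(x = c(0, 1, 2),
                                                y = c(0, 1, 2)))
  expect_equal(seg$area, 0, tolerance = 1e-12)
  expect_equal(max(seg$width, seg$height), 2 * sqrt(2), tolerance = 1e-9)

  # random point sets: calipers area matches a 0.1-degree brute-force
  # minimum within 0.5%, and never exceeds the axis-aligned box
  set.seed(31)
  for (i in 1:30) {
    n <- sample(3:20, 1)
    P <- cbind(runif(n, -5, 5), runif(n, -5, 5))
    r <- minimum_enclosing_rectangle(data.frame(x = P[, 1], y = P[, 2]))
    expect_lte(r$area, brute_min_rect_area(P) * 1.005)
    bbox <- (max(P[, 1]) - min(P[, 1])) * (max(P[, 2]) - min(P[, 2]))
    expect_lte(r$area, bbox + 1e-9)
  }
})

test_that("rotate_to_axes is a rigid motion into [0,w] x [0,h]", {
  diamond <- data.frame(gene_id = paste0("g", 1:4),
                        x = c(0, 1, 2, 1), y = c(1, 0, 1, 2))
  r <- minimum_enclosing_rectangle(diamond)
  rot <- rotate_to_axes(diamond, r)
  expect_true(all(rot$x >= -1e-9 & rot$x <= r$width + 1e-9))
  expect_true(all(rot$y >= -1e-9 & rot$y <= r$height + 1e-9))
  # the diamond fills a sqrt(2) x sqrt(2) square with a corner at origin
  expect_equal(sort(c(min(rot$x), min(rot$y))), c(0, 0), tolerance = 1e-9)
  expect_equal(max(rot$x), sqrt(2), tolerance = 1e-9)
  expect_equal(max(rot$y), sqrt(2), tolerance = 1e-9)

  # pairwise distances preserved
  d0 <- dist(cbind(diamond$x, diamond$y))
  d1 <- dist(cbind(rot$x, rot$y))
  expect_equal(as.numeric(d1), as.numeric(d0), tolerance = 1e-9)

  # angle-0 rectangle: pure translation
  sq <- data.frame(gene_id = paste0("p", 1:3),
                   x = c(2, 3, 2.5), y = c(5, 5, 6))
  rs <- minimum_enclosing_rectangle(sq)
  rot2 <- rotate_to_axes(sq, rs)
  shift <- c(rot2$x[1] - sq$x[1], rot2$y[1] - sq$y[1])
  expect_equal(rot2$x, sq$x + shift[1], tolerance = 1e-9)
  expect_equal(rot2$y, sq$y + shift[2], tolerance = 1e-9)
})

test_that("rasterization conserves genes and renders collision means", {
  # unit-square corners at 2x2: four distinct pixels, one gene each
  corners <- data.frame(gene_id = paste0("g", 1:4),
                        x = c(0, 1, 1, 0), y = c(0, 0, 1, 1))
  lay <- rasterize(corners, c(2L, 2L))
  expect_equal(length(lay$collision_groups), 4L)
  expect_true(all(lengths(lay$collision_groups) == 1L))
  expect_true(all(lay$pixel >= 0L & lay$pixel <= 1L))

  # coincident points share a pixel
  co <- data.frame(gene_id = c("a", "b", "c"),
                   x = c(0.5, 0.5, 0), y = c(0.5, 0.5, 0))
  lay2 <- rasterize(co, c(8L, 8L))
  key <- paste(lay2$pixel[, 1], lay2$pixel[, 2])
  expect_identical(key[1], key[2])
  expect_equal(sum(lengths(lay2$collision_groups)), 3L)

  # conservation on random clouds
  set.seed(11)
  for (i in 1:20) {
    n <- sample(5:60, 1)
    cl <- data.frame(gene_id = sprintf("g%02d", 1:n),
                     x = runif(n), y = runif(n))
    layr <- rasterize(cl, c(5L, 7L))
    expect_equal(sum(lengths(layr$collision_groups)), n)
    expect_setequal(unlist(layr$collision_groups), cl$gene_id)
  }

  # rendering: collision group (0.2, 0.4) -> 0.3; background exactly 0
  img <- render_sample(c(0.2, 0.4, 0.8), lay2)
  shared <- lay2$pixel[1, ] + 1L
  expect_equal(img$pixels[shared[1], shared[2]], 0.3)
  occupied <- unique(lay2$pixel)
  expect_equal(sum(img$pixels != 0), nrow(occupied))

  # constant input renders the constant on every occupied pixel
  imgc <- render_sample(rep(0.6, 3), lay2)
  expect_equal(imgc$pixels[imgc$pixels != 0],
               rep(0.6, length(lay2$collision_groups)), tolerance = 1e-12)

  # linearity: render(a * x) = a * render(x)
  img_half <- render_sample(c(0.1, 0.2, 0.4), lay2)
  expect_equal(img_half$pixels * 2,
               render_sample(c(0.2, 0.4, 0.8), lay2)$pixels)

  expect_error(render_sample(c(0.1, 0.2), lay2), "alignment")
})

test_that("dataset rendering commutes with class averaging", {
  em <- tiny_em(m = 30L, n_per_class = 8L)
  sc <- fisher_scores(em)
  cats <- categorize_genes(sc, 3L)
  coords <- lda_project_genes(em, cats)
  rect <- minimum_enclosing_rectangle(coords)
  lay <- rasterize(rotate_to_axes(coords, rect), c(8L, 8L))

  imgs <- render_dataset(em, lay)
  expect_length(imgs, ncol(em$values))
  expect_true(all(vapply(imgs, function(im)
    all(dim(im$pixels) == c(8L, 8L)), logical(1))))
  expect_identical(vapply(imgs, function(im) im$label, ""),
                   as.character(em$labels))

  # mean of rendered AD images == render of the mean AD expression
  ad <- which(em$labels == "AD")
  mean_img <- Reduce(`+`, lapply(imgs[ad], function(im) im$pixels)) / length(ad)
  direct <- render_sample(rowMeans(em$values[, ad]), lay)
  expect_equal(mean_img, direct$pixels, tolerance = 1e-12)

  # gene-set mismatch
  expect_error(render_dataset(subset_expression(em, genes = 1:10), lay),
               "alignment")
})

test_that("pixel layouts serialize to canonical JSON and back", {
  set.seed(4)
  cl <- data.frame(gene_id = sprintf("g%02d", 1:25),
                   x = runif(25), y = runif(25))
  lay <- rasterize(cl, c(6L, 6L))
  dir <- withr::local_tempdir()
  p1 <- file.path(dir, "a.json"); p2 <- file.path(dir, "b.json")
  write_layout_json(lay, p1)
  write_layout_json(lay, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))

  back <- read_layout_json(p1)
  expect_identical(back$gene_ids, lay$gene_ids)
  expect_equal(back$pixel, lay$pixel, ignore_attr = TRUE)
  expect_equal(back$image_width, lay$image_width)
  img_a <- render_sample(runif(25, 0, 1), lay)
  img_b <- render_sample(runif(25, 0, 1), back)  # same layout semantics
  expect_equal(dim(img_b$pixels), dim(img_a$pixels))
})
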