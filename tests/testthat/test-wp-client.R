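search_json <- function() {
  jsonlite::toJSON(list(result = list(
    list(id = "WP2795", name = "Cardiac Hypertrophic Response",
         species = "Homo sapiens", revision = "73920"),
    list(id = "WP1", name = "Other", species = "Homo sapiens", revision = "1"))),
    auto_unbox = TRUE)
}

test_that("pathway search parses mock hits into pathway references", {
  tp <- mock_transport(list(findPathwaysByText = search_json()))
  refs <- find_pathways("hypertrophy", config = wp_config(), transport = tp)
  expect_equal(nrow(refs), 2)
  expect_equal(refs$wpid, c("WP2795", "WP1"))
  expect_equal(refs$organism[1], "Homo sapiens")
})

test_that("search errors are distinguishable: service vs transport vs cancelled", {
  err500 <- function(url, token, t) list(status_code = 500L, text = "boom")
  expect_error(find_pathways("q", transport = err500), class = "gpml_service_error")

  down <- function(url, token, t) stop("connection refused")
  e <- tryCatch(find_pathways("q", transport = down), error = function(e) e)
  expect_s3_class(e, "gpml_transport_error")
  expect_false(inherits(e, "gpml_cancelled"))
})

test_that("a pre-cancelled token short-circuits before any network call", {
  tp <- mock_transport(list(findPathwaysByText = search_json()))
  tok <- cancel(cancellation_token())
  expect_error(find_pathways("q", token = tok, transport = tp),
               class = "gpml_cancelled")
  expect_equal(attr(tp, "calls")$n, 0L)  # zero transport invocations
})

test_that("GPML download round-trips the packaged fixture through the mock", {
  gpml_txt <- paste(readLines(system.file("extdata", "synthetic-canonical.gpml",
                                          package = "gpmlgraph")), collapse = "\n")
  tp <- mock_transport(list(`pwId=WP2795` = gpml_txt))
  txt <- get_pathway_gpml("WP2795", transport = tp, config = wp_config())
  doc <- parse_gpml(txt)
  expect_equal(doc, read_gpml(system.file("extdata", "synthetic-canonical.gpml",
                                          package = "gpmlgraph")))
})

test_that("malformed and unknown pathway ids fail as contracted", {
  tp <- mock_transport(list(`pwId=WP2795` = "<Pathway/>"))
  expect_error(get_pathway_gpml("2795", transport = tp), "malformed")
  expect_error(get_pathway_gpml("WP404", transport = tp),
               class = "gpml_not_found")
})

test_that("cancellation mid-transfer aborts quickly and leaves no cache entry", {
  cache <- file.path(tempfile("wpcache"))
  cfg <- wp_config(cache_dir = cache)
  stalled <- make_stalled_transport(cancel_after = 3L, poll_interval = 0.02)
  tok <- cancellation_token()
  e <- tryCatch(get_pathway_gpml("WP2795", token = tok, config = cfg,
                                 transport = stalled),
                error = function(e) e)
  returned_at <- Sys.time()
  expect_s3_class(e, "gpml_cancelled")
  latency <- as.numeric(returned_at - attr(stalled, "state")$cancelled_at,
                        units = "secs")
  expect_lt(latency, 0.25)
  # no partial pathway left behind
  expect_false(dir.exists(cache) && length(list.files(cache)) > 0)
})

test_that("the on-disk cache is written once and bypassable", {
  cache <- tempfile("wpcache")
  cfg <- wp_config(cache_dir = cache)
  gpml_txt <- write_gpml(make_fixture(fixture_spec()))
  tp <- mock_transport(list(`pwId=WP2795` = gpml_txt))
  t1 <- get_pathway_gpml("WP2795", transport = tp, config = cfg)
  t2 <- get_pathway_gpml("WP2795", transport = tp, config = cfg)
  expect_equal(attr(tp, "calls")$n, 1L)          # second hit served from cache
  expect_equal(parse_gpml(t1), parse_gpml(t2))
  t3 <- get_pathway_gpml("WP2795", transport = tp, config = cfg, use_cache = FALSE)
  expect_equal(attr(tp, "calls")$n, 2L)          # bypass goes to the wire
  expect_equal(parse_gpml(t3), parse_gpml(t1))
})

test_that("tokens are sticky and observable", {
  tok <- cancellation_token()
  expect_false(is_cancelled(tok))
  cancel(tok)
  expect_true(is_cancelled(tok))
  cancel(tok)                       # idempotent
  expect_true(is_cancelled(tok))
  expect_false(is_cancelled(NULL))  # absent token never cancels
})

test_that("key=value config files round-trip into a client configuration", {
  f <- tempfile(fileext = ".conf")
  writeLines(c("# local mirror", "base_url = http://localhost:8000/wp",
               "timeout_seconds = 5", "gpml_path = /{wpid}.gpml"), f)
  cfg <- read_wp_config(f)
  expect_equal(cfg$base_url, "http://localhost:8000/wp")
  expect_equal(cfg$timeout_seconds, 5)
  expect_equal(cfg$gpml_path, "/{wpid}.gpml")
})

test_that("the default curl transport serves file:// URLs offline", {
  dir <- tempfile("mockwp"); dir.create(dir)
  write_gpml(make_fixture(fixture_spec()), file.path(dir, "WP77.gpml"))
  cfg <- wp_config(base_url = paste0("file://", dir), gpml_path = "/{wpid}.gpml")
  txt <- get_pathway_gpml("WP77", config = cfg, transport = curl_transport,
                          use_cache = FALSE)
  expect_equal(parse_gpml(txt), make_fixture(fixture_spec()))
})
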