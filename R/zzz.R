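# Some minimal containers ship R without a reachable Olson timezone
# database (named-zone conversions silently behave like UTC). Named zones
# are load-bearing here -- night/day classification hinges on correct local
# times -- so point TZDIR at a usable database if the default is broken.
.onLoad <- function(libname, pkgname) {
  probe <- function() {
    a <- suppressWarnings(as.POSIXct("2018-12-21 01:00:00", tz = "America/Denver"))
    b <- suppressWarnings(as.POSIXct("2018-12-21 01:00:00", tz = "UTC"))
    isTRUE(as.numeric(a) - as.numeric(b) == 7 * 3600)
  }
  if (probe()) return(invisible())
  candidates <- c(
    file.path(dirname(dirname(R.home())), "share", "zoneinfo"), # conda layout
    "/usr/share/zoneinfo", "/usr/lib/zoneinfo", "/etc/zoneinfo")
  for (cand in candidates) {
    if (file.exists(file.path(cand, "America", "Denver"))) {
      Sys.setenv(TZDIR = cand)
      if (probe()) return(invisible())
    }
  }
  packageStartupMessage(
    "facetrap: no usable timezone database found; named-zone conversions ",
    "may behave like UTC (set TZDIR manually)")
  invisible()
}
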