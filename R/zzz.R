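.onLoad <- function(libname, pkgname) {
  # single-threaded BLAS: keeps results bit-reproducible and avoids thread
  # contention when the process is pinned to one core
  invisible(cpp_set_blas_threads(1L))
}
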