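// The training loop allocates and frees multi-hundred-megabyte im2col
// buffers every minibatch; with glibc defaults each one is a fresh mmap
// whose pages must be zero-faulted, which costs more than the matmuls.
// Raising the mmap/trim thresholds once at load keeps those buffers on the
// reusable heap.
#include <Rcpp.h>
#ifdef __GLIBC__
#include <malloc.h>
#endif

// [[Rcpp::export]]
void nn_tune_allocator() {
#ifdef __GLIBC__
  mallopt(M_MMAP_THRESHOLD, 512 * 1024 * 1024);
  mallopt(M_TRIM_THRESHOLD, 512 * 1024 * 1024);
#endif
}
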