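#ifndef ALIGNTAILS_H
#define ALIGNTAILS_H

#include <Rcpp.h>

int sw_score_core(const int *x, int lx, const int *y, int ly,
                  const Rcpp::IntegerMatrix &mdef,
                  const Rcpp::IntegerMatrix &mreg,
                  const int *xregion, int openCost, int extCost);

#endif
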