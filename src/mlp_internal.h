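#ifndef MOTIVRL_MLP_INTERNAL_H
#define MOTIVRL_MLP_INTERNAL_H

#include <Rcpp.h>

double mlp_act_fun(double z, int code, double alpha);
double mlp_act_deriv(double a, int code, double alpha);

// In-place semi-gradient update through one selected output (see mlp.cpp).
void mlp_backprop_selected(Rcpp::List Ws, Rcpp::List bs,
                           Rcpp::IntegerVector act, Rcpp::NumericVector alpha,
                           Rcpp::List cache, int k, double scale);

#endif
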