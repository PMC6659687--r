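#ifndef VIVIPHY_H
#define VIVIPHY_H
#include <RcppArmadillo.h>
arma::mat mk_pmat(const arma::mat& Q, double t);
#endif
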