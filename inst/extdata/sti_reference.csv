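accession,sti_t1,sti_t2,sti_combined
AC61,1.13,1.07,1.10
AC13,0.37,0.13,0.25
AC54,0.98,0.98,0.98
AC39,1.08,1.00,1.04
AC42,1.11,0.95,1.03
AC64,1.09,0.99,1.04
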