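indicator,group,x,n
fmd,full_men,738,10654
fmd,full_women,1799,12366
fmd,S1_men,206,3806
fmd,S1_women,102,816
fmd,SK_men,30,322
fmd,SK_women,579,4305
depression,full_men,554,10724
depression,full_women,1195,12435
depression,S1_men,133,3828
depression,S1_women,59,817
depression,SK_men,26,322
depression,SK_women,364,4310
srh_not_good,full_men,1558,10714
srh_not_good,full_women,2224,12421
srh_not_good,S1_men,461,3825
srh_not_good,S1_women,117,815
srh_not_good,SK_men,48,322
srh_not_good,SK_women,624,4309
hypertension,full_men,2595,10724
hypertension,full_women,2542,12435
hypertension,S1_men,800,3828
hypertension,S1_women,122,817
hypertension,SK_men,69,322
hypertension,SK_women,647,4310
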