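table,quantity,class,stat,printed_value,note
covariates,age_years,,mean,34.2,
covariates,age_years,,sd,6.5,
covariates,breastfeeding_months,,mean,7.1,
covariates,breastfeeding_months,,sd,6.0,
covariates,storage_days,,mean,14.7,
covariates,storage_days,,sd,7.3,
counts,n_total,,mean,99873,
counts,n_total,,sd,31978.52,
counts,n_individual,,mean,83825.83,
counts,n_individual,,sd,25450.30,
counts,pct_individual,,mean,84.75,printed as the complement of the agglomerate percentage (100 - 15.25); the individual-percentage column itself averages 84.64 because one sample's classes do not sum to its total
counts,pct_individual,,sd,6.93,printed SD equals the agglomerate-percentage column SD; the individual-percentage column SD is 6.91
counts,n_agglomerate,,mean,15963.83,
counts,n_agglomerate,,sd,10738.49,
counts,pct_agglomerate,,mean,15.25,
counts,pct_agglomerate,,sd,6.93,
metrics,d10,total,mean,4.91,
metrics,d10,total,sd,0.66,
metrics,d10,individual,mean,4.36,
metrics,d10,individual,sd,0.54,
metrics,d10,agglomerate,mean,8.00,
metrics,d10,agglomerate,sd,0.92,
metrics,pn10,total,mean,2.77,
metrics,pn10,total,sd,0.37,
metrics,pn10,individual,mean,2.70,
metrics,pn10,individual,sd,0.34,
metrics,pn10,agglomerate,mean,4.77,
metrics,pn10,agglomerate,sd,0.86,
metrics,pn50,total,mean,4.21,
metrics,pn50,total,sd,0.60,
metrics,pn50,individual,mean,4.00,
metrics,pn50,individual,sd,0.55,
metrics,pn50,agglomerate,mean,7.18,
metrics,pn50,agglomerate,sd,0.98,
metrics,pn90,total,mean,7.56,
metrics,pn90,total,sd,1.06,
metrics,pn90,individual,mean,6.28,
metrics,pn90,individual,sd,0.86,
metrics,pn90,agglomerate,mean,11.96,
metrics,pn90,agglomerate,sd,1.76,
correlations,storage_vs_d10,total,r,-0.481,
correlations,storage_vs_pn10,agglomerate,r,-0.631,
correlations,storage_vs_pn50,individual,r,-0.554,printed row labels for the two Pn50 correlations cannot be reconciled with recomputation from the per-sample tables
correlations,storage_vs_pn50,agglomerate,r,-0.526,printed row labels for the two Pn50 correlations cannot be reconciled with recomputation from the per-sample tables
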