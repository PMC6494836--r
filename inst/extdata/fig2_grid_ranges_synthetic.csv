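topology,name,low,high,scale
MAO_PATH,ddc.vmax,1,50,log
MAO_PATH,ddc.km,0.02,2,log
MAO_PATH,ddc.ki.dopamine,0.1,10,log
MAO_PATH,mao.vmax,0.05,2,log
MAO_PATH,mao.km,0.05,2,log
MAO_PATH,mao.ki.amine,0.1,10,log
MAO_PATH,mao.ki.DHPAA,0.1,10,log
MAO_PATH,k_cond,0.1,10,log
MAO_PATH,feed_rate,1,4,linear
MAO_PATH,k_drain,0.05,1,log
DDC_DHPAAS_PATH,ddc.vmax,1,50,log
DDC_DHPAAS_PATH,ddc.km,0.02,2,log
DDC_DHPAAS_PATH,ddc.ki.dopamine,0.1,10,log
DDC_DHPAAS_PATH,dhpaas.vmax,1,50,log
DDC_DHPAAS_PATH,dhpaas.km,0.01,1,log
DDC_DHPAAS_PATH,dhpaas.ki.dopamine,0.1,10,log
DDC_DHPAAS_PATH,dhpaas.ki.DHPAA,0.1,10,log
DDC_DHPAAS_PATH,k_cond,0.1,10,log
DDC_DHPAAS_PATH,feed_rate,1,4,linear
DDC_DHPAAS_PATH,k_drain,0.05,1,log
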