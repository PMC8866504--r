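pre,post,type
ASEL,AIYL,chem
ASEL,AIYR,chem
ASEL,AIBL,chem
ASEL,AIBR,chem
ASER,AIYL,chem
ASER,AIYR,chem
ASER,AIBL,chem
ASER,AIBR,chem
AIYL,AIZL,chem
AIYR,AIZR,chem
AIYL,RIAL,chem
AIYR,RIAR,chem
AIYL,RIBL,chem
AIYR,RIBR,chem
AIZL,RIAL,chem
AIZR,RIAR,chem
AIZL,RIML,chem
AIZR,RIMR,chem
AIZL,AIBR,chem
AIZR,AIBL,chem
AIZL,SMBDL,chem
AIZR,SMBDR,chem
AIZL,SMBVL,chem
AIZR,SMBVR,chem
AIBL,RIMR,chem
AIBR,RIML,chem
AIBL,RIBL,chem
AIBR,RIBR,chem
AIBL,AVBL,chem
AIBR,AVBR,chem
AIBL,RIVL,chem
AIBR,RIVR,chem
RIAL,SMBDL,chem
RIAR,SMBDR,chem
RIAL,SMBVL,chem
RIAR,SMBVR,chem
RIAL,RIVL,chem
RIAR,RIVR,chem
RIML,AVAL,chem
RIMR,AVAR,chem
RIML,AVBL,chem
RIMR,AVBR,chem
RIML,AVEL,chem
RIMR,AVER,chem
RIVL,SMBVL,chem
RIVR,SMBVL,chem
RIBL,AVBL,chem
RIBR,AVBR,chem
RIBL,SMBDL,chem
RIBR,SMBDR,chem
AVEL,AVAL,chem
AVER,AVAR,chem
AVEL,AVAR,chem
AVER,AVAL,chem
AVEL,AVDL,chem
AVER,AVDR,chem
AVEL,RIML,chem
AVER,RIMR,chem
AVAL,AVDL,chem
AVAR,AVDR,chem
AVDL,AVAL,chem
AVDR,AVAR,chem
AVDL,AVAR,chem
AVDR,AVAL,chem
PVCL,AVAL,chem
PVCR,AVAR,chem
PVCL,AVAR,chem
PVCR,AVAL,chem
PVCL,AVBL,chem
PVCR,AVBR,chem
PVCL,AVBR,chem
PVCR,AVBL,chem
PVCL,AVDL,chem
PVCR,AVDR,chem
PVCL,AVEL,chem
PVCR,AVER,chem
AIBL,AIBR,chem
AIBL,ASEL,chem
AIBL,AVDL,chem
AIBL,PVCR,chem
AIBL,RIVR,chem
AIBR,AIBL,chem
AIBR,ASEL,chem
AIBR,AVDL,chem
AIBR,PVCR,chem
AIBR,RIVL,chem
AIYL,AIBL,chem
AIYL,ASER,chem
AIYL,AVDL,chem
AIYL,PVCR,chem
AIYL,RIVL,chem
AIYL,SMBVL,chem
AIYR,AIZL,chem
AIYR,AVBL,chem
AIYR,AVER,chem
AIYR,RIML,chem
AIYR,SMBDR,chem
AIZL,AIYR,chem
AIZL,AVAR,chem
AIZL,AVEL,chem
AIZL,RIBL,chem
AIZL,SMBDR,chem
AIZR,AIZL,chem
AIZR,AVBL,chem
AIZR,AVER,chem
AIZR,RIBR,chem
AIZR,SMBVL,chem
AVAL,AIZL,chem
AVAL,AVBL,chem
AVAL,PVCL,chem
AVAL,RIBR,chem
AVAL,SMBDL,chem
AVAR,AIBR,chem
AVAR,ASEL,chem
AVAR,AVDL,chem
AVAR,RIAL,chem
AVAR,RIMR,chem
AVAR,SMBVL,chem
AVBL,AIYR,chem
AVBL,AVAL,chem
AVBL,AVDR,chem
AVBL,RIAL,chem
AVBL,RIMR,chem
AVBL,SMBVL,chem
AVBR,AIYR,chem
AVBR,AVAL,chem
AVBR,AVEL,chem
AVBR,RIAR,chem
AVBR,RIVL,chem
AVBR,SMBVR,chem
AVDL,AIZL,chem
AVDL,AVBR,chem
AVDL,PVCR,chem
AVDL,RIML,chem
AVDL,SMBDR,chem
AVDR,AIYL,chem
AVDR,ASER,chem
AVDR,AVER,chem
AVDR,RIBL,chem
AVDR,RIVR,chem
AVEL,AIBL,chem
AVEL,AIZR,chem
AVEL,AVDR,chem
AVEL,RIAR,chem
AVEL,RIVR,chem
AVER,AIBL,chem
AVER,AIZR,chem
AVER,AVDL,chem
AVER,RIAL,chem
AVER,RIVL,chem
AVER,SMBVR,chem
PVCL,AIZL,chem
PVCL,AVER,chem
PVCL,RIBR,chem
PVCL,SMBDL,chem
PVCR,AIBR,chem
PVCR,ASEL,chem
PVCR,RIAL,chem
PVCR,RIMR,chem
PVCR,SMBVL,chem
RIAL,AIYR,chem
RIAL,AVAL,chem
RIAL,AVDR,chem
RIAL,RIAR,chem
RIAL,RIVR,chem
RIAR,AIYL,chem
RIAR,ASER,chem
RIAR,AVDL,chem
RIAR,PVCR,chem
RIAR,RIMR,chem
RIBL,AIBR,chem
RIBL,ASEL,chem
RIBL,AVDL,chem
RIBL,PVCR,chem
RIBL,RIMR,chem
RIBL,SMBVR,chem
RIBR,AIZL,chem
RIBR,AVAL,chem
RIBR,AVEL,chem
RIBR,RIAR,chem
RIBR,RIVR,chem
RIML,AIBR,chem
RIML,ASEL,chem
RIML,AVDR,chem
RIML,RIAR,chem
RIML,RIVR,chem
RIMR,AIBL,chem
RIMR,AIZR,chem
RIMR,AVDL,chem
RIMR,RIAL,chem
RIMR,RIVL,chem
RIMR,SMBVR,chem
ASEL,ASER,gap
AIYL,AIYR,gap
AIZL,AIZR,gap
AIBL,AIBR,gap
RIAL,RIAR,gap
RIML,RIMR,gap
AVEL,AVER,gap
AVAL,AVAR,gap
AVBL,AVBR,gap
AVDL,AVDR,gap
PVCL,PVCR,gap
RIBL,RIBR,gap
SMBDL,SMBDR,gap
SMBVL,SMBVR,gap
AVAL,AVDL,gap
AVAL,RIML,gap
AVAL,AVEL,gap
AVBL,RIBL,gap
AVBL,PVCL,gap
AIYL,RIBL,gap
RIAL,SMBDL,gap
AVAR,AVDR,gap
AVAR,RIMR,gap
AVAR,AVER,gap
AVBR,RIBR,gap
AVBR,PVCR,gap
AIYR,RIBR,gap
RIAR,SMBDR,gap
AIBL,AIYL,gap
AIBL,PVCR,gap
AIBR,AVBL,gap
AIBR,RIMR,gap
AIYL,RIAL,gap
AIYR,AVEL,gap
AIZL,AVDL,gap
AIZR,AVAR,gap
AIZR,RIBR,gap
AVAL,RIMR,gap
AVBL,AVDR,gap
AVBR,PVCL,gap
AVDL,RIBR,gap
AVEL,PVCL,gap
AVER,RIBR,gap
PVCR,RIML,gap
RIBR,RIMR,gap
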